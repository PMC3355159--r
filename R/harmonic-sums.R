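# Closed forms for the weighted harmonic sums behind the linear-time
# evaluation of the partial-list measures. All are exact identities,
# obtained by exchanging the order of summation (sum_i i * H_{i+k} =
# sum_m (1/m) * sum over the i whose harmonic index reaches m); each is
# O(1) given a harmonic table covering the required indices.

# T(n, k) = sum_{i=1}^{n} i * H_{i+k}
sum_i_h <- function(n, k, H) {
  if (n <= 0L) return(0)
  h_nk <- hval(H, n + k)
  h_k1 <- hval(H, k + 1L)
  n <- as.numeric(n)              # keep products out of integer range
  k <- as.numeric(k)
  n * (n + 1) / 2 * h_nk -
    0.5 * (n * (n - 1) / 2 - k * (n - 1) + k * (k + 1) * (h_nk - h_k1))
}

# U(n) = sum_{i=1}^{n} i * H_{2i-1}
sum_i_h_odd <- function(n, H) {
  if (n <= 0L) return(0)
  h_odd <- hval(H, 2L * n - 1L)
  h_even <- hval(H, 2L * n)
  h_n <- hval(H, n)
  n <- as.numeric(n)
  n * (n + 1) / 2 * h_odd -
    0.5 * ((n - 1) * (n + 2) / 4 + n^2 / 4 -
             0.25 * (h_even - 0.5 * h_n))
}

# V(n) = sum_{i=1}^{n} i * H_{2i} = U(n) + n/2
sum_i_h_even <- function(n, H) sum_i_h_odd(n, H) + n / 2

# Rectangular Canberra block sum
#   W(a, b, p) = sum_{i=a}^{p} sum_{j=b}^{p} |i-j| / (i+j)
# via |i-j|/(i+j) = 1 - 2*min(i,j)/(i+j) and the closed forms above.
# Drives the unselected-features term T3; O(1) given H up to 2p.
canberra_block_sum <- function(a, b, p, H) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  if (b > p) return(0)
  m1 <- if (a < b) {
    (sum_i_h(b - 1L, p, H) - sum_i_h(a - 1L, p, H)) -
      (sum_i_h(b - 1L, b - 1L, H) - sum_i_h(a - 1L, b - 1L, H))
  } else 0
  m2 <- (sum_i_h(p, p, H) - sum_i_h(b - 1L, p, H)) -
    (sum_i_h_odd(p, H) - sum_i_h_odd(b - 1L, H))
  m3 <- (sum_i_h(p, p, H) - sum_i_h(b - 1L, p, H)) -
    (sum_i_h_even(p, H) - sum_i_h_even(b - 1L, H))
  # the sum is nonnegative by construction; guard against cancellation
  # noise when the true value is (near) zero
  max(0, as.numeric(p - a + 1) * as.numeric(p - b + 1) - 2 * (m1 + m2 + m3))
}

# Tail sum S(r, a, p) = sum_{j=a}^{p} |r-j| / (r+j), vectorised over r.
# Drives the exclusive-features term T2; O(1) per rank given H up to 2p.
canberra_tail_sum <- function(r, a, p, H) {
  out <- numeric(length(r))
  jmax <- pmin(p, r - 1L)                 # j < r branch: 2r/(r+j) - 1
  lo <- jmax >= a
  if (any(lo)) {
    rl <- r[lo]; jm <- jmax[lo]
    out[lo] <- 2 * rl * (hval(H, rl + jm) - hval(H, rl + a - 1L)) -
      (jm - a + 1)
  }
  jmin <- pmax(a, r)                      # j >= r branch: 1 - 2r/(r+j)
  hi <- jmin <= p
  if (any(hi)) {
    rh <- r[hi]; jn <- jmin[hi]
    out[hi] <- out[hi] + (p - jn + 1) -
      2 * rh * (hval(H, rh + p) - hval(H, rh + jn - 1L))
  }
  pmax(out, 0)
}
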