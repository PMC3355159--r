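# Shared fixtures and independent oracles. The oracles deliberately use
# nothing from the package's evaluation paths: plain recursive
# enumeration of permutations and literal summation of the Canberra
# distance over all completion pairs.

# One conventional seed for every stochastic test in the suite.
TEST_SEED <- 20260925L

# All n! permutations of 1..n as rows (n <= 8).
perms_all <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  if (n == 1L) return(matrix(1L))
  sub <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    shifted <- sub + (sub >= k)
    cbind(k, shifted, deparse.level = 0L)
  }))
}

canberra_vec <- function(a, b) sum(abs(a - b) / (a + b))

# Exhaustive mean Canberra distance to the identity over S_p.
exhaustive_expected <- function(p) {
  P <- perms_all(p)
  mean(apply(P, 1L, canberra_vec, b = seq_len(p)))
}

# Literal mean over every pair of completions of two partial lists,
# in pure R. Only for tiny deficits.
r_completion_mean <- function(L1, L2, u) {
  p <- u$size
  r1 <- r2 <- integer(p)
  r1[match(L1$items, u$features)] <- seq_len(L1$length)
  r2[match(L2$items, u$features)] <- seq_len(L2$length)
  m1 <- which(r1 == 0L)
  m2 <- which(r2 == 0L)
  P1 <- perms_all(length(m1))
  P2 <- perms_all(length(m2))
  tot <- 0
  for (i in seq_len(nrow(P1))) {
    R1 <- r1
    if (length(m1) > 0L) R1[m1[P1[i, ]]] <- L1$length + seq_along(m1)
    for (j in seq_len(nrow(P2))) {
      R2 <- r2
      if (length(m2) > 0L) R2[m2[P2[j, ]]] <- L2$length + seq_along(m2)
      tot <- tot + canberra_vec(R1, R2)
    }
  }
  tot / (nrow(P1) * nrow(P2))
}

# Random partial-list pair over a fresh universe; deficits bounded so
# that full enumeration stays feasible.
random_instance <- function(p, l1, l2) {
  u <- feature_universe(size = p)
  list(u = u,
       L1 = ranked_list(u$features[sample.int(p, l1)], u),
       L2 = ranked_list(u$features[sample.int(p, l2)], u))
}

skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
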