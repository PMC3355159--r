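# Seeded generators for the simulation settings used to characterise the
# measures: uniformly random complete lists, random partial (top-l)
# lists with or without a shared support, and the maximally distant
# ordering of a fixed support. All randomness goes through R's RNG; a
# `seed` argument makes each generator a pure function of its inputs and
# is recorded on the result.

#' Uniformly random complete ranked lists
#'
#' @param n Number of lists (>= 2).
#' @param p Universe size (>= 2).
#' @param seed Optional integer seed; when supplied the result is a pure
#'   function of `(n, p, seed)`.
#' @return A [list_set()] of `n` independent uniform permutations of the
#'   auto-named universe, with the seed attached as an attribute.
#' @export
random_complete_lists <- function(n, p, seed = NULL) {
  n <- check_count(n, "n", min = 2L)
  p <- check_count(p, "p", min = 2L)
  if (!is.null(seed)) set.seed(seed)
  u <- feature_universe(size = p)
  lists <- lapply(seq_len(n), function(i) {
    ranked_list(u$features[sample.int(p)], u)
  })
  S <- list_set(lists, u)
  attr(S, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  S
}

#' Random partial (top-l) ranked lists
#'
#' Each list has length `l`. With `shared_support = TRUE` one support of
#' `l` features is drawn once and every list is an independent uniform
#' ordering of it — the setting behind the "random" rows of the
#' reference simulations; otherwise every list independently draws both
#' its support and its order (equivalently, the top-`l` head of a uniform
#' permutation).
#'
#' @param n Number of lists (>= 2).
#' @param p Universe size.
#' @param l List length, `l <= p`.
#' @param seed Optional integer seed.
#' @param shared_support All lists over one common support? Default
#'   `FALSE`.
#' @return A [list_set()], seed attached as an attribute.
#' @export
random_partial_lists <- function(n, p, l, seed = NULL,
                                 shared_support = FALSE) {
  n <- check_count(n, "n", min = 2L)
  p <- check_count(p, "p", min = 2L)
  l <- check_count(l, "l", min = 1L)
  if (l > p) stop_input("list length l = %d exceeds universe size p = %d", l, p)
  if (!is.null(seed)) set.seed(seed)
  u <- feature_universe(size = p)
  if (shared_support) {
    support <- u$features[sample.int(p, l)]
    lists <- lapply(seq_len(n), function(i) {
      ranked_list(support[sample.int(l)], u)
    })
  } else {
    lists <- lapply(seq_len(n), function(i) {
      ranked_list(u$features[sample.int(p, l)], u)
    })
  }
  S <- list_set(lists, u)
  attr(S, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  S
}

#' Ordering maximizing the Canberra distance to the identity
#'
#' Exhaustively searches the `l!` permutations of `1..l` for one whose
#' Canberra distance to the identity is maximal. By right-invariance of
#' the distance, applying this ordering to any fixed support realizes the
#' maximally distant pair of lists sharing that support. The search is
#' capped at `l = 10` (3.6 million permutations); beyond that it refuses
#' rather than run for hours — consult the combinatorial literature for
#' the structural construction of the maximizer at larger `l`.
#'
#' @param l Support size, `1 <= l <= 10`.
#' @return Integer permutation of `1..l` with attribute `distance`, the
#'   maximal Canberra distance.
#' @examples
#' max_distant_ordering(2)  # the swap (2, 1), distance 2/3
#' @export
max_distant_ordering <- function(l) {
  l <- check_count(l, "l", min = 1L)
  if (l > 10L)
    stop_cap(paste0("exhaustive search is capped at l = 10 (l = %d requested);",
                    " use the published construction of the Canberra",
                    " maximizer for longer lists"), l)
  res <- cpp_max_canberra_perm(l)
  structure(res$perm, distance = res$distance)
}

#' Replicated stability of random complete lists
#'
#' Draws `replicates` independent sets of `n_lists` uniformly random
#' complete lists over `p` features and returns the mean and variance of
#' the normalized complete-mode stability indicator across replicates —
#' the quantity tabulated when showing that random list sets sit near 1.
#'
#' @param n_lists Lists per set (>= 2).
#' @param p Universe size.
#' @param replicates Number of independent sets (>= 2; default 10).
#' @param seed Optional integer seed.
#' @return Named numeric vector `c(mean = , variance = )`.
#' @export
replicate_table1 <- function(n_lists, p, replicates = 10L, seed = NULL) {
  replicates <- check_count(replicates, "replicates", min = 2L)
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(replicates), function(r) {
    S <- random_complete_lists(n_lists, p)
    stability_indicator(S, mode = "complete", normalized = TRUE)
  }, numeric(1))
  c(mean = mean(vals), variance = stats::var(vals))
}

#' Reference pairs of length-10 partial lists at p = 10^c
#'
#' Reproduces the characterisation of the measure on three canonical
#' pairs of length-10 lists sharing one support inside a universe of
#' `10^c` features: identical lists, a single random pair of orderings,
#' and the maximally distant pair. Identical and maximally distant rows
#' are deterministic; the random row is one draw governed by `seed`.
#'
#' @param c Exponent of the universe size, 2 to 5.
#' @param seed Optional integer seed for the random pair.
#' @return `data.frame` with columns `lists` (`identical`, `random`,
#'   `max_distant`), `core` and `complete` (both normalized).
#' @export
replicate_table2 <- function(c, seed = NULL) {
  c <- check_count(c, "c", min = 2L)
  if (c > 5L) stop_input("`c` must lie in 2..5 (got %d)", c)
  if (!is.null(seed)) set.seed(seed)
  p <- as.integer(10^c)
  l <- 10L
  u <- feature_universe(size = p)
  H <- harmonic_table(2L * p)
  support <- u$features[seq_len(l)]
  L_id <- ranked_list(support, u)

  bd_id <- measure_closed(L_id, L_id, u, H = H)

  sigma <- sample.int(l)                       # random ordering of the support
  L_rnd <- ranked_list(support[order(sigma)], u)
  bd_rnd <- measure_closed(L_id, L_rnd, u, H = H)

  tau <- max_distant_ordering(l)               # ranks of the maximizer
  L_max <- ranked_list(support[order(tau)], u)
  bd_max <- measure_closed(L_id, L_max, u, H = H)

  data.frame(
    lists = c("identical", "random", "max_distant"),
    core = c(bd_id$core_normalized, bd_rnd$core_normalized,
             bd_max$core_normalized),
    complete = c(bd_id$complete_normalized, bd_rnd$complete_normalized,
                 bd_max$complete_normalized),
    stringsAsFactors = FALSE
  )
}
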