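#' Per-feature extraction statistics of a list set
#'
#' For every feature of the universe, counts the lists containing it (its
#' number of extractions) and the mean of its 1-based ranks over those
#' lists. Features extracted by no list get `mean_position = NA`.
#'
#' @param S A [list_set()] (one list suffices).
#' @return `data.frame` with one row per universe feature, in universe
#'   order: columns `feature`, `extractions`, `mean_position`.
#' @export
extraction_stats <- function(S) {
  if (!inherits(S, "list_set")) stop_input("`S` must be a list_set")
  feats <- S$universe$features
  p <- S$universe$size
  counts <- integer(p)
  sumpos <- numeric(p)
  for (L in S$lists) {
    idx <- match(L$items, feats)
    counts[idx] <- counts[idx] + 1L
    sumpos[idx] <- sumpos[idx] + seq_along(idx)
  }
  data.frame(
    feature = feats,
    extractions = counts,
    mean_position = ifelse(counts > 0L, sumpos / pmax(counts, 1L), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Borda aggregation of a set of ranked lists
#'
#' Derives a single "optimal" list from a set of B lists: features are
#' ordered by decreasing extraction count, ties broken by increasing mean
#' position, residual ties by universe order (making the output fully
#' deterministic). On complete lists this ordering coincides with the
#' classical Borda count by ascending total rank.
#'
#' @param S A [list_set()].
#' @param include_unextracted Keep features appearing in no list? They are
#'   appended after all extracted features, in universe order. Default
#'   `FALSE`: the aggregate contains only selected features.
#' @return A `data.frame` of class `borda_list`, ordered by the Borda
#'   rule: columns `feature`, `extractions`, `mean_position`,
#'   `borda_rank`.
#' @examples
#' u <- feature_universe(c("A", "B", "C"))
#' S <- list_set(list(c("A", "B"), c("A")), u)
#' borda_list(S)
#' @export
borda_list <- function(S, include_unextracted = FALSE) {
  st <- extraction_stats(S)
  key_pos <- ifelse(is.na(st$mean_position), Inf, st$mean_position)
  ord <- order(-st$extractions, key_pos, seq_len(nrow(st)))
  out <- st[ord, , drop = FALSE]
  if (!include_unextracted) out <- out[out$extractions > 0L, , drop = FALSE]
  out$borda_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("borda_list", "data.frame")
  out
}

#' @export
print.borda_list <- function(x, n = 10L, ...) {
  cat(sprintf("Borda list: %d features\n", nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE, ...)
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}
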