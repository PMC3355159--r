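#' Feature universe
#'
#' The full set of `p` distinct feature identifiers every ranked list
#' draws from (e.g. all probes on an array). Either pass the identifiers
#' explicitly or only a size, in which case features are auto-named
#' `f000001, f000002, ...`; the measures depend on identity only through
#' membership, but a fixed universe order keeps Borda tie-breaking
#' deterministic.
#'
#' @param features Character vector of distinct identifiers, or `NULL`.
#' @param size Universe size `p`, used when `features` is `NULL`.
#' @return An object of class `feature_universe` with elements `features`
#'   and `size`.
#' @examples
#' feature_universe(size = 4)
#' feature_universe(c("TP53", "ERG", "AR"))
#' @export
feature_universe <- function(features = NULL, size = NULL) {
  if (is.null(features)) {
    if (is.null(size)) stop_input("provide `features` or `size`")
    size <- check_count(size, "size", min = 1L)
    features <- sprintf("f%06d", seq_len(size))
  } else {
    features <- as.character(features)
    if (length(features) < 1L) stop_input("universe must hold at least one feature")
    if (anyNA(features) || any(features == ""))
      stop_input("universe features must be non-missing, non-empty strings")
    if (anyDuplicated(features))
      stop_input("duplicate feature in universe: '%s'",
                 features[duplicated(features)][1L])
    if (!is.null(size) && size != length(features))
      stop_input("`size` (%d) disagrees with length of `features` (%d)",
                 size, length(features))
  }
  structure(list(features = features, size = length(features)),
            class = "feature_universe")
}

#' @export
print.feature_universe <- function(x, ...) {
  cat(sprintf("Feature universe: p = %d (%s%s)\n", x$size,
              paste(utils::head(x$features, 4L), collapse = ", "),
              if (x$size > 4L) ", ..." else ""))
  invisible(x)
}

#' Ranked (partial) list
#'
#' An ordered, duplicate-free selection of `l <= p` features out of a
#' universe: the top-`l` head of some full ranking. Position `k` carries
#' rank `k` (1-based, rank 1 = best). An empty list is legal.
#'
#' @param items Character vector of feature identifiers, best first.
#' @param universe A [feature_universe()].
#' @return An object of class `ranked_list` with elements `items` and
#'   `length`.
#' @examples
#' u <- feature_universe(size = 6)
#' ranked_list(c("f000003", "f000001"), u)
#' @export
ranked_list <- function(items, universe) {
  check_universe(universe)
  items <- as.character(items)
  if (anyNA(items)) stop_input("ranked list contains missing identifiers")
  if (anyDuplicated(items))
    stop_input("duplicate feature in ranked list: '%s'",
               items[duplicated(items)][1L])
  missing <- setdiff(items, universe$features)
  if (length(missing) > 0L)
    stop_input("feature not in universe: '%s'", missing[1L])
  structure(list(items = items, length = length(items)),
            class = "ranked_list")
}

check_universe <- function(universe) {
  if (!inherits(universe, "feature_universe"))
    stop_input("`universe` must be a feature_universe")
  universe
}

check_ranked_list <- function(L, universe) {
  if (!inherits(L, "ranked_list")) stop_input("expected a ranked_list")
  if (!all(L$items %in% universe$features))
    stop_input("ranked list holds features outside the universe")
  L
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("Ranked list (l = %d): %s%s\n", x$length,
              paste(utils::head(x$items, 8L), collapse = " > "),
              if (x$length > 8L) " > ..." else ""))
  invisible(x)
}

#' Dual rank assignment of a ranked list
#'
#' Maps each listed feature to its 1-based rank. Features outside the
#' list are absent from the result (no sentinel rank is invented).
#'
#' @param L A [ranked_list()].
#' @param universe The [feature_universe()] the list lives in.
#' @return Named integer vector: `result[feature] = rank`.
#' @examples
#' u <- feature_universe(c("g1", "g2", "g3", "g4"))
#' dualize(ranked_list(c("g3", "g1"), u), u)  # g3 = 1, g1 = 2
#' @export
dualize <- function(L, universe) {
  check_universe(universe)
  check_ranked_list(L, universe)
  stats::setNames(seq_len(L$length), L$items)
}

#' Support partition of two partial lists
#'
#' Splits the universe into the features appearing in both lists (size
#' `z`), in exactly one of them, and in neither (`u` features). These
#' four blocks drive the T1/T2/T3 terms of the Complete measure and
#' always satisfy `z + (l1 - z) + (l2 - z) + u = p`.
#'
#' @param L1,L2 [ranked_list()] objects over `universe`.
#' @param universe The shared [feature_universe()].
#' @return An object of class `support_partition`: list with `common`,
#'   `only_first`, `only_second` (character vectors) and the sizes `z`,
#'   `l1`, `l2`, `u`, `p`.
#' @export
partition_support <- function(L1, L2, universe) {
  check_universe(universe)
  check_ranked_list(L1, universe)
  check_ranked_list(L2, universe)
  common <- intersect(L1$items, L2$items)
  z <- length(common)
  u <- universe$size - (L1$length + L2$length - z)
  structure(list(
    common = common,
    only_first = setdiff(L1$items, common),
    only_second = setdiff(L2$items, common),
    z = z, l1 = L1$length, l2 = L2$length, u = u, p = universe$size
  ), class = "support_partition")
}

#' Set of ranked lists over one universe
#'
#' @param lists List of [ranked_list()] objects (or character vectors,
#'   which are promoted) sharing `universe`. Lengths may differ.
#' @param universe The shared [feature_universe()].
#' @return An object of class `list_set` with elements `lists`,
#'   `universe` and `B` (number of lists).
#' @export
list_set <- function(lists, universe) {
  check_universe(universe)
  if (!is.list(lists) || length(lists) < 1L)
    stop_input("`lists` must be a non-empty list of ranked lists")
  lists <- lapply(lists, function(L) {
    if (inherits(L, "ranked_list")) check_ranked_list(L, universe)
    else ranked_list(L, universe)
  })
  structure(list(lists = lists, universe = universe, B = length(lists)),
            class = "list_set")
}

#' @export
print.list_set <- function(x, ...) {
  cat(sprintf("Set of %d ranked lists over p = %d features (lengths %s)\n",
              x$B, x$universe$size,
              paste(range(vapply(x$lists, `[[`, 1L, "length")),
                    collapse = "-")))
  invisible(x)
}
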