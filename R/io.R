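# Plain-text ranked-list files: one list per line, tokens separated by
# tabs, commas or whitespace. Blank lines and lines starting with '#' are
# ignored. With `has_ids = TRUE` the first token of each line is a list
# label, not a feature.

split_tokens <- function(line, sep) {
  tok <- if (sep == "whitespace") strsplit(trimws(line), "[ \t]+")[[1]]
         else strsplit(line, sep, fixed = TRUE)[[1]]
  tok <- trimws(tok)
  tok[tok != ""]
}

detect_sep <- function(lines) {
  if (any(grepl("\t", lines, fixed = TRUE))) "\t"
  else if (any(grepl(",", lines, fixed = TRUE))) ","
  else "whitespace"
}

#' Read a set of ranked lists from a plain-text file
#'
#' @param path File with one ranked list per line (best feature first).
#' @param universe The feature universe: a [feature_universe()], a
#'   character vector of identifiers, or the path of a file holding one
#'   identifier per line. May be `NULL` when `universe_size` is given.
#' @param universe_size Implicit universe: the observed tokens (sorted)
#'   padded with auto-named features up to this size. The measures depend
#'   on feature identity only through membership, so an implicit universe
#'   is exact whenever the true identifiers of the unselected features do
#'   not matter.
#' @param sep Token separator: `"\t"`, `","`, `"whitespace"`, or `NULL`
#'   to auto-detect (tab, then comma, then whitespace).
#' @param has_ids First token of each line is a list label? Default
#'   `FALSE`.
#' @return A [list_set()]. Validation failures (duplicate token, token
#'   outside the universe, empty file) raise labelled input errors naming
#'   the line or token.
#' @export
read_ranked_lists <- function(path, universe = NULL, universe_size = NULL,
                              sep = NULL, has_ids = FALSE) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !grepl("^\\s*#", raw))
  if (length(keep) == 0L) stop_input("empty ranked-list file: %s", path)
  if (is.null(sep)) sep <- detect_sep(raw[keep])

  rows <- lapply(keep, function(i) {
    tok <- split_tokens(raw[i], sep)
    if (has_ids) tok <- tok[-1]
    if (anyDuplicated(tok))
      stop_input("line %d of %s: duplicate token '%s'",
                 i, path, tok[duplicated(tok)][1L])
    tok
  })

  if (is.null(universe)) {
    if (is.null(universe_size))
      stop_input("provide `universe` or `universe_size`")
    seen <- sort(unique(unlist(rows)))
    universe_size <- check_count(universe_size, "universe_size", min = 1L)
    if (length(seen) > universe_size)
      stop_input("%d distinct tokens observed but universe_size = %d",
                 length(seen), universe_size)
    pad <- setdiff(sprintf("f%06d", seq_len(universe_size)), seen)
    universe <- feature_universe(c(seen, pad[seq_len(universe_size - length(seen))]))
  } else if (is.character(universe) && length(universe) == 1L &&
             file.exists(universe)) {
    feats <- trimws(readLines(universe, warn = FALSE))
    universe <- feature_universe(feats[nzchar(feats) & !grepl("^#", feats)])
  } else if (!inherits(universe, "feature_universe")) {
    universe <- feature_universe(universe)
  }

  lists <- lapply(seq_along(rows), function(k) {
    bad <- setdiff(rows[[k]], universe$features)
    if (length(bad) > 0L)
      stop_input("line %d of %s: token '%s' not in the universe",
                 keep[k], path, bad[1L])
    ranked_list(rows[[k]], universe)
  })
  list_set(lists, universe)
}

#' Write a set of ranked lists to a plain-text file
#'
#' One list per line, inverse of [read_ranked_lists()].
#'
#' @param S A [list_set()].
#' @param path Output path.
#' @param sep Token separator (default tab).
#' @export
write_ranked_lists <- function(S, path, sep = "\t") {
  if (!inherits(S, "list_set")) stop_input("`S` must be a list_set")
  writeLines(vapply(S$lists, function(L) paste(L$items, collapse = sep),
                    character(1)), path)
  invisible(path)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

#' Serialize a report to TSV or JSON
#'
#' Deterministic plain-text serialization of the package's result
#' objects. Floats are printed at `digits` decimals (default 6). JSON
#' output carries the full context of a stability computation: mode,
#' normalization flag, the normalizer `E(p)` and the generator seed when
#' one was recorded.
#'
#' @param x A `stability_report`, `borda_list` or `canberra_breakdown`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Decimal places for floating-point values.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json"), digits = 6) {
  UseMethod("write_report")
}

#' @export
write_report.stability_report <- function(x, path, format = c("tsv", "json"),
                                          digits = 6) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- apply(x$matrix, 1L, function(row)
      paste(fmt_num(row, digits), collapse = "\t"))
    writeLines(c(sprintf("# canberra stability matrix: B=%d p=%d mode=%s normalized=%s indicator=%s E(p)=%s seed=%s",
                         x$B, x$p, x$mode, tolower(x$normalized),
                         fmt_num(x$indicator, digits),
                         fmt_num(x$normalizer, digits),
                         ifelse(is.na(x$seed), "NA", x$seed)),
                 lines), path)
  } else {
    obj <- list(
      mode = x$mode, normalized = x$normalized,
      normalizer = round(x$normalizer, digits),
      indicator = round(x$indicator, digits),
      B = x$B, p = x$p, seed = x$seed,
      matrix = round(x$matrix, digits)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.borda_list <- function(x, path, format = c("tsv", "json"),
                                    digits = 6) {
  format <- match.arg(format)
  if (format == "tsv") {
    body <- sprintf("%s\t%d\t%s\t%d", x$feature, x$extractions,
                    fmt_num(x$mean_position, digits), x$borda_rank)
    writeLines(c("feature\textractions\tmean_position\tborda_rank", body),
               path)
  } else {
    obj <- list(entries = data.frame(
      feature = x$feature, extractions = x$extractions,
      mean_position = round(x$mean_position, digits),
      borda_rank = x$borda_rank))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.canberra_breakdown <- function(x, path,
                                            format = c("tsv", "json"),
                                            digits = 6) {
  format <- match.arg(format)
  fields <- c("t1", "t2", "t3", "core", "complete", "normalizer",
              "core_normalized", "complete_normalized")
  if (format == "tsv") {
    writeLines(c("quantity\tvalue",
                 sprintf("%s\t%s", fields,
                         fmt_num(unlist(x[fields]), digits)),
                 sprintf("%s\t%d", c("p", "l1", "l2", "z", "u"),
                         unlist(x[c("p", "l1", "l2", "z", "u")]))), path)
  } else {
    obj <- c(lapply(x[fields], function(v) round(v, digits)),
             x[c("p", "l1", "l2", "z", "u", "strategy")])
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
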