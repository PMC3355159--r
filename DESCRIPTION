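Package: canberralists
Title: Canberra Dissimilarity, Stability and Borda Aggregation for
    Partial Ranked Lists
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares ranked feature lists of unequal length with the
    Canberra dissimilarity on permutation groups. A partial (top-k) list
    is identified with the set of its completions to full permutations;
    the dissimilarity between two partial lists is the mean Canberra
    distance over all completion pairs, evaluated either by explicit
    enumeration, by a per-feature expectation form, or by a
    harmonic-number closed form that runs in linear time. Values are
    normalized by the exact expected Canberra distance on the full
    permutation group, yielding the Complete and Core measures, a
    stability indicator for sets of ranked lists (as used when assessing
    the reproducibility of biomarker signatures across resampled feature
    selection runs), and Borda aggregation of a list set into a single
    optimal list.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
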