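#' Fisher-exact term enrichment of a called feature set
#'
#' For each term, tests the 2x2 table of called/uncalled x in-term/out-of-term
#' features with the two-sided Fisher exact test, reports fold enrichment
#' `(overlap/|called|) / (|term|/|universe|)` (values < 1 are
#' under-representation) and BH-adjusts across terms.
#'
#' @param called character vector of called feature ids (subset of universe).
#' @param universe character vector of all tested feature ids.
#' @param term_map tibble with columns `term` and `feature_id` (one row per
#'   membership); features outside the universe are ignored.
#' @return tibble per term: sizes, overlap, `fold_enrichment`, `p`, `padj`.
#' @export
fisher_enrichment <- function(called, universe, term_map) {
  universe <- unique(universe)
  called <- unique(called)
  if (!all(called %in% universe))
    stop_validation("called set must be a subset of the universe")
  tm <- term_map |>
    dplyr::filter(.data$feature_id %in% universe) |>
    dplyr::distinct(.data$term, .data$feature_id)
  if (nrow(tm) == 0)
    return(tibble::tibble(term = character(), term_size = integer(),
                          n_called = integer(), overlap = integer(),
                          fold_enrichment = numeric(), p = numeric(),
                          padj = numeric()))
  N <- length(universe); K <- length(called)
  res <- tm |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      term_size = dplyr::n(),
      overlap = sum(.data$feature_id %in% called),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_called = K,
      fold_enrichment = (.data$overlap / K) / (.data$term_size / N),
      p = purrr::map2_dbl(.data$overlap, .data$term_size, function(a, ts) {
        tab <- matrix(c(a, K - a, ts - a, N - K - ts + a), 2)
        # two-sided sums can exceed 1 by floating-point epsilon
        min(fisher.test(tab, alternative = "two.sided")$p.value, 1)
      })
    ) |>
    dplyr::mutate(padj = bh_adjust(.data$p)) |>
    dplyr::select("term", "term_size", "n_called", "overlap",
                  "fold_enrichment", "p", "padj") |>
    dplyr::arrange(.data$p)
  res
}
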