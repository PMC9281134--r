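#' Normalize counts by library size and transcript length
#'
#' Size factors are median-of-ratios over features with a nonzero geometric
#' mean. Transcript counts are additionally normalized by length in kb; the
#' same quantities enter the GLMs as offsets `log(size factor * length/1000)`
#' (transcripts) or `log(size factor)` (miRNAs), preserving the NB
#' mean-variance relation while matching the stated mean model.
#'
#' @param experiment a [count_experiment()].
#' @return list with `size_factors` (named), `offsets` (features x samples
#'   matrix), `normalized` (matrix of normalized counts) and the input
#'   `experiment`.
#' @export
normalize_counts <- function(experiment) {
  counts <- experiment$counts
  zero_sample <- colSums(counts) == 0
  if (any(zero_sample))
    stop_validation(paste0("all-zero sample(s): ",
                           paste(colnames(counts)[zero_sample], collapse = ", ")))
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop_validation("no feature has nonzero counts in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    median(exp(log(cnt) - log_geo[use])))
  sf <- sf / exp(mean(log(sf)))  # geometric-mean centering

  len_kb <- if (experiment$kind == "transcript" && !is.null(experiment$lengths))
    unname(experiment$lengths[rownames(counts)]) / 1000 else
    rep(1, nrow(counts))
  denom <- outer(len_kb, sf)
  list(
    size_factors = sf,
    offsets = log(denom),
    normalized = counts / denom,
    experiment = experiment
  )
}

#' Discard lowly expressed features
#'
#' Transcript features are dropped when their length-normalized counts,
#' aggregated across samples, fall strictly below `threshold`; miRNA features
#' use raw counts. The default aggregation is the sum across all samples
#' (a per-sample reading of the threshold would discard most features).
#'
#' @param experiment a [count_experiment()].
#' @param normalized optional result of [normalize_counts()]; computed
#'   internally when missing.
#' @param threshold strict lower bound (19): features with aggregate < 19 go.
#' @param aggregate `"sum"` (default), `"mean"` or `"max"` across samples.
#' @return the filtered [count_experiment()].
#' @export
filter_low_expression <- function(experiment, normalized = NULL,
                                  threshold = 19,
                                  aggregate = c("sum", "mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (nrow(experiment$counts) == 0) return(experiment)
  basis <- if (experiment$kind == "mirna") experiment$counts else {
    if (is.null(normalized)) normalized <- normalize_counts(experiment)
    normalized$normalized
  }
  agg <- switch(aggregate,
                sum = rowSums(basis),
                mean = rowMeans(basis),
                max = apply(basis, 1, max))
  keep <- agg >= threshold
  count_experiment(
    experiment$counts[keep, , drop = FALSE], experiment$samples,
    lengths = if (!is.null(experiment$lengths)) experiment$lengths[keep],
    kind = experiment$kind
  )
}
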