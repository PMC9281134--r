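#' Principal components of expression profiles
#'
#' PCA of `log2(normalized count + 1)` with feature centering and no scaling
#' (a plain stand-in for a regularized-log transform). Samples are the
#' observations.
#'
#' @param normalized normalized count matrix (features x samples) from
#'   [normalize_counts()], or a [count_experiment()] (normalized internally).
#' @param samples optional sample metadata joined onto the coordinates (taken
#'   from the experiment when one is given).
#' @param n_components number of components to return.
#' @return tibble of sample coordinates with metadata; attribute
#'   `percent_variance` holds the per-component explained-variance
#'   percentages (non-negative, non-increasing, summing to <= 100).
#' @export
pca_profile <- function(normalized, samples = NULL, n_components = 4) {
  if (inherits(normalized, "count_experiment")) {
    samples <- samples %||% normalized$samples
    normalized <- normalize_counts(normalized)$normalized
  }
  if (ncol(normalized) < 2) stop_validation("PCA needs at least 2 samples")
  lt <- log2(normalized + 1)
  keep <- apply(lt, 1, function(r) stats::var(r) > 0)
  if (!any(keep)) {
    warning("constant expression matrix; PCA undefined")
    keep <- rep(TRUE, nrow(lt))
  }
  pc <- prcomp(t(lt[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  out <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE],
                           rownames = "sample")
  if (!is.null(samples)) out <- dplyr::left_join(out, samples, by = "sample")
  attr(out, "percent_variance") <- pct[seq_len(k)]
  out
}

#' Plot the first two expression principal components
#'
#' @param pca result of [pca_profile()] (needs `species`/`structure` columns
#'   for the aesthetics when available).
#' @return a ggplot.
#' @export
plot_pca <- function(pca) {
  pv <- attr(pca, "percent_variance")
  gg <- ggplot2::ggplot(pca, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", pv[1]),
      y = sprintf("PC2 (%.1f%%)", pv[2])
    ) +
    ggplot2::theme_minimal()
  if (all(c("species", "structure") %in% names(pca))) {
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$species,
                                          shape = .data$structure), size = 3)
  } else {
    gg + ggplot2::geom_point(size = 3)
  }
}

#' MA-style plot of one comparison of a differential-expression result
#'
#' @param de a `de_result` from [run_de_analysis()].
#' @param test comparison to show (default the interaction / DDEG test).
#' @return a ggplot of mean expression vs log2 fold change, consensus calls
#'   highlighted.
#' @export
plot_ma <- function(de, test = "interaction") {
  mean_expr <- tibble::tibble(
    feature_id = rownames(de$normalized),
    base_mean = rowMeans(de$normalized)
  )
  df <- de$calls |>
    dplyr::filter(.data$test == !!test) |>
    dplyr::left_join(mean_expr, by = "feature_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$base_mean,
                                   y = .data$log2fc_lrt,
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change",
                  title = test) +
    ggplot2::theme_minimal()
}

#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, test = "interaction", ...) {
  plot_ma(object, test = test)
}
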