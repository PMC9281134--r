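# The 7 pairwise contrasts of the 2 species x 3 structure design, as
# combinations of the 6 coefficients (intercept, speciesB, flower, fruit,
# B:flower, B:fruit). Species contrasts within each structure, and the two
# structure transitions within each species.
de_contrasts <- function() {
  list(
    species_B_vs_A_in_bud    = c(0, 1, 0, 0, 0, 0),
    species_B_vs_A_in_flower = c(0, 1, 0, 0, 1, 0),
    species_B_vs_A_in_fruit  = c(0, 1, 0, 0, 0, 1),
    flower_vs_bud_in_A       = c(0, 0, 1, 0, 0, 0),
    fruit_vs_flower_in_A     = c(0, 0, -1, 1, 0, 0),
    flower_vs_bud_in_B       = c(0, 0, 1, 0, 1, 0),
    fruit_vs_flower_in_B     = c(0, 0, -1, 1, -1, 1)
  )
}

contrast_estimates <- function(fit, contrast) {
  est <- as.numeric(fit$beta %*% contrast)
  se2 <- vapply(seq_along(est), function(g)
    as.numeric(t(contrast) %*% fit$cov[, , g] %*% contrast), numeric(1))
  list(estimate = est, var_unscaled = se2)
}

#' Likelihood-ratio test of the species x structure interaction
#'
#' Compares the full model (`species + structure + species:structure`) to the
#' reduced main-effects model per feature: statistic
#' `2 (logLik_full - logLik_reduced)` on 2 df against the chi-squared tail.
#' Features significant here are the differently differentially expressed
#' genes (DDEGs): genes whose expression change between two structures
#' differs between the species. Interaction log2 fold changes are reported
#' per structure transition (flower vs bud, fruit vs flower).
#'
#' @param fit_full,fit_reduced `nb_fit` objects sharing dispersions.
#' @return tibble: feature_id, the two transition interaction log2FCs,
#'   `log2fc` (the larger-magnitude one, signed), `stat`, `df`, `p` (`NA`
#'   for unconverged fits).
#' @export
test_interaction <- function(fit_full, fit_reduced) {
  stat <- pmax(2 * (fit_full$loglik - fit_reduced$loglik), 0)
  ok <- fit_full$converged & fit_reduced$converged
  p <- ifelse(ok, pchisq(stat, df = 2, lower.tail = FALSE), NA_real_)
  l_fl <- fit_full$beta_log2[, 5]
  l_fr <- fit_full$beta_log2[, 6] - fit_full$beta_log2[, 5]
  pick <- ifelse(abs(l_fl) >= abs(l_fr), l_fl, l_fr)
  tibble::tibble(
    feature_id = fit_full$feature_id,
    test = "interaction",
    log2fc_flower_bud = unname(l_fl),
    log2fc_fruit_flower = unname(l_fr),
    log2fc = unname(pick),
    stat = stat, df = 2, p = p
  )
}

#' Wald tests of the seven pairwise contrasts
#'
#' Species B vs A within each structure (3 contrasts) and the two structure
#' transitions within each species (4 contrasts), as linear combinations of
#' the full-model coefficients. Significant features are the differentially
#' expressed genes (DEGs) of each comparison.
#'
#' @param fit_full full-model `nb_fit`.
#' @param contrasts named list of contrast vectors; defaults to the design's
#'   seven.
#' @return tibble: feature_id, test (contrast name), log2fc, stat (Wald z),
#'   df, p.
#' @export
test_contrasts <- function(fit_full, contrasts = de_contrasts()) {
  purrr::imap_dfr(contrasts, function(cc, nm) {
    ce <- contrast_estimates(fit_full, cc)
    z <- ce$estimate / sqrt(pmax(ce$var_unscaled, 1e-12))
    tibble::tibble(
      feature_id = fit_full$feature_id,
      test = nm,
      log2fc = ce$estimate / log(2),
      stat = z, df = 1,
      p = ifelse(fit_full$converged, 2 * pnorm(-abs(z)), NA_real_)
    )
  })
}

# Quasi-likelihood engine: trended-dispersion NB fits, per-feature quasi
# dispersion from the residual deviance moderated with an empirical-Bayes
# squeeze, then F-tests for the interaction and the contrasts.
ql_tests <- function(fit_full, fit_reduced, contrasts = de_contrasts()) {
  df_res <- fit_full$df_residual
  s2 <- pmax(fit_full$deviance / df_res, 1e-10)
  sq <- limma::squeezeVar(s2, df = df_res)
  df_total <- df_res + sq$df.prior
  s2_post <- sq$var.post

  int_stat <- pmax(fit_reduced$deviance - fit_full$deviance, 0) / 2 / s2_post
  ok <- fit_full$converged & fit_reduced$converged
  l_fl <- fit_full$beta_log2[, 5]
  l_fr <- fit_full$beta_log2[, 6] - fit_full$beta_log2[, 5]
  pick <- ifelse(abs(l_fl) >= abs(l_fr), l_fl, l_fr)
  interaction <- tibble::tibble(
    feature_id = fit_full$feature_id, test = "interaction",
    log2fc_flower_bud = unname(l_fl), log2fc_fruit_flower = unname(l_fr),
    log2fc = unname(pick),
    stat = int_stat, df = 2,
    p = ifelse(ok, pf(int_stat, 2, df_total, lower.tail = FALSE), NA_real_)
  )
  contr <- purrr::imap_dfr(contrasts, function(cc, nm) {
    ce <- contrast_estimates(fit_full, cc)
    f <- ce$estimate^2 / pmax(ce$var_unscaled, 1e-12) / s2_post
    tibble::tibble(
      feature_id = fit_full$feature_id, test = nm,
      log2fc = ce$estimate / log(2),
      stat = f, df = 1,
      p = ifelse(fit_full$converged,
                 pf(f, 1, df_total, lower.tail = FALSE), NA_real_)
    )
  })
  dplyr::bind_rows(interaction, contr)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA`s pass through and do
#'   not count toward the number of tests.
#' @return adjusted p-values controlling the false discovery rate.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_validation("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0) return(out)
  o <- order(p[idx], decreasing = TRUE)
  out[idx[o]] <- pmin(1, cummin(m / (m:1) * p[idx][o]))
  out
}

#' Consensus significance calls across the two engines
#'
#' A feature is called for a given test iff, in *both* engines, its
#' BH-adjusted p-value is at most `alpha` and its |log2 fold change| strictly
#' exceeds `lfc`; only this overlap between the two methods is reported.
#' Direction is the sign of the LRT-engine log2FC.
#'
#' @param tests_lrt,tests_ql per-test result tibbles (with `padj`) from the
#'   LRT/Wald and quasi-likelihood engines.
#' @param alpha FDR threshold (0.001).
#' @param lfc strict |log2FC| threshold (1).
#' @return tibble joined by feature and test with per-engine padj/log2fc,
#'   `called` and `direction`.
#' @export
call_significant <- function(tests_lrt, tests_ql, alpha = 0.001, lfc = 1) {
  a <- dplyr::select(tests_lrt, "feature_id", "test",
                     log2fc_lrt = "log2fc", p_lrt = "p", padj_lrt = "padj")
  b <- dplyr::select(tests_ql, "feature_id", "test",
                     log2fc_ql = "log2fc", p_ql = "p", padj_ql = "padj")
  dplyr::inner_join(a, b, by = c("feature_id", "test")) |>
    dplyr::mutate(
      called = !is.na(.data$padj_lrt) & !is.na(.data$padj_ql) &
        .data$padj_lrt <= alpha & .data$padj_ql <= alpha &
        abs(.data$log2fc_lrt) > lfc & abs(.data$log2fc_ql) > lfc,
      direction = dplyr::if_else(.data$called,
                                 dplyr::if_else(.data$log2fc_lrt > 0,
                                                "up", "down"),
                                 NA_character_)
    )
}

#' Run the full two-engine differential-expression analysis
#'
#' Normalizes, filters low-expressed features, estimates dispersions, fits
#' the full and reduced NB GLMs under two engines (likelihood-ratio/Wald with
#' trend-shrunk dispersions; quasi-likelihood F with moderated quasi
#' dispersions), BH-adjusts per test family and per engine, and reports the
#' consensus calls: the interaction test defines the DDEGs, the seven
#' pairwise contrasts the DEGs.
#'
#' @param experiment a [count_experiment()].
#' @param alpha FDR threshold for calls (0.001).
#' @param lfc strict |log2FC| threshold (1).
#' @param low_count low-expression threshold (19), see
#'   [filter_low_expression()].
#' @param aggregate aggregation for the low-expression filter.
#' @param prior_df trend-shrinkage prior df for dispersion estimation (30).
#' @return object of class `de_result`: `calls` (consensus tibble), `tests`
#'   (both engines, long), `dispersions`, `size_factors`, `normalized`
#'   counts, the filtered `experiment` and the thresholds used.
#' @export
run_de_analysis <- function(experiment, alpha = 0.001, lfc = 1,
                            low_count = 19, aggregate = "sum",
                            prior_df = 30) {
  filtered <- filter_low_expression(experiment, threshold = low_count,
                                    aggregate = aggregate)
  if (nrow(filtered$counts) == 0)
    stop_validation("no features left after low-expression filtering")
  norm <- normalize_counts(filtered)
  X_full <- design_matrix(filtered$samples)
  X_red <- design_matrix(filtered$samples, reduced = TRUE)
  disp <- estimate_dispersion(filtered, offsets = norm$offsets,
                              design = X_full, prior_df = prior_df)

  fit_full_1 <- fit_nb_glm(filtered$counts, X_full, norm$offsets, disp$alpha)
  fit_red_1 <- fit_nb_glm(filtered$counts, X_red, norm$offsets, disp$alpha)
  tests_lrt <- dplyr::bind_rows(
    test_interaction(fit_full_1, fit_red_1),
    test_contrasts(fit_full_1)
  ) |> adjust_per_family()

  fit_full_2 <- fit_nb_glm(filtered$counts, X_full, norm$offsets,
                           disp$alpha_trend)
  fit_red_2 <- fit_nb_glm(filtered$counts, X_red, norm$offsets,
                          disp$alpha_trend)
  tests_ql <- ql_tests(fit_full_2, fit_red_2) |> adjust_per_family()

  calls <- call_significant(tests_lrt, tests_ql, alpha = alpha, lfc = lfc)
  structure(
    list(calls = calls,
         tests = dplyr::bind_rows(
           dplyr::mutate(tests_lrt, engine = "lrt"),
           dplyr::mutate(tests_ql, engine = "ql")),
         dispersions = disp, size_factors = norm$size_factors,
         normalized = norm$normalized, experiment = filtered,
         alpha = alpha, lfc = lfc,
         fits = list(full_lrt = fit_full_1, full_ql = fit_full_2)),
    class = "de_result"
  )
}

# BH within each test family (each contrast, and the interaction, separately)
adjust_per_family <- function(tests) {
  tests |>
    dplyr::group_by(.data$test) |>
    dplyr::mutate(padj = bh_adjust(.data$p)) |>
    dplyr::ungroup()
}

#' @export
print.de_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<de_result> %d features tested, alpha = %g, |log2FC| > %g\n",
              nrow(x$experiment$counts), x$alpha, x$lfc))
  print(g)
  invisible(x)
}

#' Consensus call table of a differential-expression result
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return the consensus tibble (one row per feature x test).
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) x$calls

#' Per-comparison call summary
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return tibble of up/down/total consensus calls per test; the interaction
#'   row counts the DDEGs.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  x$calls |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(
      n_tested = sum(!is.na(.data$padj_lrt)),
      n_called = sum(.data$called),
      n_up = sum(.data$called & .data$direction == "up", na.rm = TRUE),
      n_down = sum(.data$called & .data$direction == "down", na.rm = TRUE),
      .groups = "drop"
    )
}
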