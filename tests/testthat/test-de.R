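test_that("size factors and length normalization behave as stated", {
  set.seed(80)
  counts <- matrix(rnbinom(50 * 18, mu = 100, size = 10), 50,
                   dimnames = list(sprintf("f%02d", 1:50),
                                   toy_samples()$sample))
  lengths <- setNames(rep(2000, 50), rownames(counts))
  exp0 <- toy_experiment(counts, lengths)

  # identical columns: all size factors 1
  same <- counts; same[] <- rep(counts[, 1], 18)
  n_same <- normalize_counts(toy_experiment(same, lengths))
  expect_true(all(abs(n_same$size_factors - 1) < 1e-12))

  # doubling one sample doubles its size factor (relative to the others)
  doubled <- counts; doubled[, 3] <- counts[, 3] * 2
  n_d <- normalize_counts(toy_experiment(doubled, lengths))
  rel <- n_d$size_factors / median(n_d$size_factors[-3])
  expect_equal(unname(rel[3]), 2, tolerance = 0.05)

  # count 100, length 2000, size factor 1 -> normalized 50
  one <- matrix(100L, 1, 18, dimnames = list("f1", toy_samples()$sample))
  n1 <- normalize_counts(toy_experiment(one, c(f1 = 2000)))
  expect_equal(unname(n1$normalized[1, 1]), 50)
  expect_equal(unname(n1$offsets[1, 1]), log(2))

  # all-zero sample is an error naming the sample
  z <- counts; z[, 5] <- 0L
  expect_error(normalize_counts(toy_experiment(z, lengths)),
               colnames(counts)[5])
})

test_that("low-expression filter applies the strict <19 rule", {
  samples <- toy_samples()
  counts <- rbind(
    f_low  = rep(1L, 18),   # sum 18.9 after normalization -> dropped
    f_edge = rep(1L, 18),   # exactly 19 -> kept
    f_high = rep(50L, 18))
  colnames(counts) <- samples$sample
  # choose lengths so length-normalized sums hit 18.9, 19 and high
  lengths <- c(f_low = 18 / 18.9 * 1000, f_edge = 18 / 19 * 1000,
               f_high = 1000)
  exp <- count_experiment(counts, samples, lengths = lengths)
  kept <- filter_low_expression(exp, threshold = 19)
  expect_setequal(rownames(kept$counts), c("f_edge", "f_high"))

  # miRNA features filter on raw counts
  mir <- count_experiment(counts, samples, kind = "mirna")
  kept_m <- filter_low_expression(mir, threshold = 19)
  expect_setequal(rownames(kept_m$counts), c("f_high"))

  # empty matrix passes through
  empty <- count_experiment(counts[0, , drop = FALSE], samples,
                            kind = "mirna")
  expect_equal(nrow(filter_low_expression(empty)$counts), 0)
})

test_that("NB GLM matches closed forms and the brute-force grid oracle", {
  # intercept-only, constant counts, zero offset: beta0 = log(c)
  X1 <- matrix(1, 6, 1)
  f <- fit_nb_glm(rep(7L, 6), X1, offsets = 0, dispersion = 1e-8)
  expect_equal(unname(f$beta[1, 1]), log(7), tolerance = 1e-7)

  # 10 random 2-condition toys: logLik within 1e-4 of a zooming grid search
  set.seed(81)
  X2 <- cbind(1, rep(c(0, 1), each = 6))
  for (i in 1:10) {
    alpha <- runif(1, 0.02, 0.5)
    beta_true <- c(runif(1, 2, 5), runif(1, -2, 2))
    offs <- rnorm(12, 0, 0.2)
    y <- rnbinom(12, mu = exp(X2 %*% beta_true + offs), size = 1 / alpha)
    fit <- fit_nb_glm(y, X2, offsets = offs, dispersion = alpha)
    oracle <- grid_oracle_loglik(y, X2, offs, alpha,
                                 center = unname(fit$beta[1, ]))
    expect_lt(abs(fit$loglik - oracle), 1e-4)
    # and the fitter's own likelihood value agrees with dnbinom
    expect_equal(fit$loglik,
                 nb_loglik_oracle(y, exp(X2 %*% fit$beta[1, ] + offs), alpha),
                 tolerance = 1e-6)
  }

  # offset identity: scaling offsets shifts only the intercept
  y <- rnbinom(12, mu = 60, size = 10)
  f0 <- fit_nb_glm(y, X2, offsets = 0, dispersion = 0.1)
  f1 <- fit_nb_glm(y, X2, offsets = log(2), dispersion = 0.1)
  expect_equal(unname(f1$beta[1, 1]), unname(f0$beta[1, 1]) - log(2),
               tolerance = 1e-6)
  expect_equal(unname(f1$beta[1, 2]), unname(f0$beta[1, 2]),
               tolerance = 1e-6)

  expect_error(fit_nb_glm(y, cbind(X2, X2[, 2]), 0, 0.1),
               class = "orthode_validation_error")
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  sim_p <- generate_count_experiment(features = 400, dispersion = 0,
                                     seed = 82)
  d_p <- estimate_dispersion(sim_p$experiment)
  expect_lte(median(d_p$alpha), 0.01)

  sim_nb <- generate_count_experiment(features = 400, dispersion = 0.1,
                                      seed = 83)
  d_nb <- estimate_dispersion(sim_nb$experiment)
  expect_gte(median(d_nb$alpha), 0.05)
  expect_lte(median(d_nb$alpha), 0.2)

  # constant-count features sit at the floor
  counts <- matrix(5L, 3, 18, dimnames = list(paste0("c", 1:3),
                                              toy_samples()$sample))
  d_c <- estimate_dispersion(toy_experiment(counts,
                                            setNames(rep(1000, 3),
                                                     rownames(counts))))
  expect_true(all(d_c$alpha_ml <= 2^-13))
})

test_that("interaction LRT and contrasts recover planted design algebra", {
  sim <- generate_count_experiment(features = 600, dispersion = 0.05,
                                   deg_fraction = 0.15, ddeg_fraction = 0.15,
                                   effect_size_log2 = 2,
                                   baseline_mean_log2 = c(8, 0.5),
                                   baseline_min = 50, seed = 84)
  exp <- sim$experiment
  norm <- normalize_counts(exp)
  Xf <- orthode:::design_matrix(exp$samples)
  Xr <- orthode:::design_matrix(exp$samples, reduced = TRUE)
  disp <- estimate_dispersion(exp, norm$offsets, Xf)
  ff <- fit_nb_glm(exp$counts, Xf, norm$offsets, disp$alpha)
  fr <- fit_nb_glm(exp$counts, Xr, norm$offsets, disp$alpha)

  ti <- test_interaction(ff, fr)
  expect_true(all(ti$p >= 0 & ti$p <= 1, na.rm = TRUE))
  # identical fits give statistic 0, p = 1
  t0 <- test_interaction(ff, ff)
  expect_true(all(t0$stat == 0))
  expect_true(all(t0$p == 1, na.rm = TRUE))

  tc <- test_contrasts(ff)
  truth <- sim$truth
  deg <- truth$feature_id[truth$is_deg]
  # planted species main effect, no interaction: all three within-structure
  # species contrasts estimate the same planted value
  sp <- tc |>
    dplyr::filter(grepl("^species", .data$test), .data$feature_id %in% deg) |>
    dplyr::left_join(truth, by = "feature_id")
  expect_equal(median(abs(sp$log2fc - sp$beta_species)), 0, tolerance = 0.2)
  per_feature_spread <- sp |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(spread = max(.data$log2fc) - min(.data$log2fc))
  expect_lt(median(per_feature_spread$spread), 1)

  # interaction-only features: species contrasts differ across structures by
  # the planted interaction coefficients
  ddeg <- truth$feature_id[truth$is_ddeg]
  int <- tc |>
    dplyr::filter(grepl("^species", .data$test), .data$feature_id %in% ddeg) |>
    tidyr::pivot_wider(id_cols = "feature_id", names_from = "test",
                       values_from = "log2fc") |>
    dplyr::left_join(truth, by = "feature_id")
  # sampling SE of the contrast difference is ~0.39 log2 units here
  # (sqrt(4 * (1/mu + alpha) / 3) / log 2), so the median absolute deviation
  # of an unbiased estimate sits near 0.26; 0.5 allows ~2x that
  expect_equal(
    median(abs((int$species_B_vs_A_in_flower - int$species_B_vs_A_in_bud) -
                 int$beta_int_flower)), 0, tolerance = 0.5)

  # null features: small fold changes, not significant
  null_id <- truth$feature_id[!truth$is_deg & !truth$is_ddeg]
  nt <- tc[tc$feature_id %in% null_id, ]
  expect_lt(median(abs(nt$log2fc)), 0.3)
  expect_lt(mean(nt$p < 0.001), 0.01)
})

test_that("planted interactions are detected with high power (derived bound)", {
  sim <- generate_count_experiment(features = 800, dispersion = 0.1,
                                   ddeg_fraction = 0.1, effect_size_log2 = 2,
                                   baseline_mean_log2 = c(8.5, 1),
                                   baseline_min = 100, seed = 85)
  de <- run_de_analysis(sim$experiment)
  lrt <- de$tests[de$tests$engine == "lrt" & de$tests$test == "interaction", ]
  truth <- sim$truth[sim$truth$is_ddeg, ]
  m <- dplyr::inner_join(lrt, truth, by = "feature_id")
  opp <- sign(m$beta_int_flower) != sign(m$beta_int_fruit)
  # opposite-sign interaction patterns carry the full noncentrality and are
  # essentially always detected; same-sign patterns are partially absorbed
  # by the main effects and sit near the detection boundary at this depth
  expect_gte(mean(m$p[opp] < 1e-4), 0.8)
  expect_gte(mean(m$p < 1e-4), 0.5)
})

test_that("BH adjustment matches the step-up rule and p.adjust exactly", {
  # hand computation of the step-up rule
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # NAs pass through without counting
  expect_equal(bh_adjust(c(0.01, NA, 0.04)),
               c(p.adjust(c(0.01, 0.04), "BH")[1], NA,
                 p.adjust(c(0.01, 0.04), "BH")[2]))
  # 100 random vectors against the independent implementation
  set.seed(86)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_identical(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "orthode_validation_error")
})

test_that("consensus calling enforces both engines and strict thresholds", {
  base <- tibble::tibble(feature_id = c("f1", "f2", "f3"),
                         test = "interaction",
                         log2fc = c(1.2, 1.0, 1.5),
                         p = c(1e-5, 1e-5, 1e-5),
                         padj = c(5e-4, 5e-4, 5e-4))
  ql <- base; ql$padj[3] <- 0.5
  calls <- call_significant(base, ql, alpha = 0.001, lfc = 1)
  expect_true(calls$called[calls$feature_id == "f1"])
  expect_equal(calls$direction[calls$feature_id == "f1"], "up")
  # |log2FC| exactly 1 is not called (strict >)
  expect_false(calls$called[calls$feature_id == "f2"])
  # engine disagreement is not called
  expect_false(calls$called[calls$feature_id == "f3"])
})

test_that("statistics are invariant to rescaling a sample with its size factor", {
  sim <- generate_count_experiment(features = 120, dispersion = 0.1,
                                   seed = 87)
  exp <- sim$experiment
  norm <- normalize_counts(exp)
  Xf <- orthode:::design_matrix(exp$samples)
  Xr <- orthode:::design_matrix(exp$samples, reduced = TRUE)

  run_stats <- function(counts, offsets) {
    ff <- fit_nb_glm(counts, Xf, offsets, 0.1)
    fr <- fit_nb_glm(counts, Xr, offsets, 0.1)
    test_interaction(ff, fr)$stat
  }
  s0 <- run_stats(exp$counts, norm$offsets)
  # scale one sample's offset by log(3): equivalent to declaring its library
  # 3x deeper; with counts unchanged the statistics must move, but scaling
  # the offsets of *all* samples leaves every statistic unchanged
  off_shift <- norm$offsets + log(3)
  s_all <- run_stats(exp$counts, off_shift)
  expect_equal(s0, s_all, tolerance = 1e-6)
})

test_that("Fisher enrichment matches arithmetic and the enumeration oracle", {
  universe <- sprintf("f%03d", 1:100)
  term_map <- tibble::tibble(term = "T1", feature_id = universe[1:10])
  called <- c(universe[1:8], universe[21:32])  # 20 called, overlap 8
  res <- fisher_enrichment(called, universe, term_map)
  expect_equal(res$fold_enrichment, 4.0)
  expect_equal(res$p, fisher_enum_oracle(8, 20, 10, 100), tolerance = 1e-10)

  # proportional overlap: fold enrichment 1, p in the no-signal region
  prop <- fisher_enrichment(c(universe[1:2], universe[31:48]), universe,
                            term_map)
  expect_equal(prop$fold_enrichment, 1.0)
  expect_gt(prop$p, 0.5)

  # random small tables against the hypergeometric enumeration
  set.seed(88)
  for (i in 1:25) {
    N <- sample(20:50, 1); K <- sample(3:(N - 3), 1)
    ts <- sample(2:(N - 2), 1)
    uni <- sprintf("u%02d", 1:N)
    cal <- sample(uni, K); in_term <- sample(uni, ts)
    r <- fisher_enrichment(cal, uni, tibble::tibble(term = "t",
                                                    feature_id = in_term))
    a <- length(intersect(cal, in_term))
    expect_equal(r$p, fisher_enum_oracle(a, K, ts, N), tolerance = 1e-9)
  }

  expect_error(fisher_enrichment(c("zzz"), universe, term_map),
               class = "orthode_validation_error")
})

test_that("PCA separates planted species structure", {
  # two duplicated sample groups with distinct means: PC1 explains ~all
  samples <- toy_samples()
  m <- matrix(10, 40, 18, dimnames = list(sprintf("f%02d", 1:40),
                                          samples$sample))
  m[, samples$species == "B"] <- 40
  m <- m + matrix(rnorm(40 * 18, 0, 0.01), 40)
  pc <- pca_profile(abs(m), samples)
  pv <- attr(pc, "percent_variance")
  expect_gt(pv[1], 99)
  expect_true(all(diff(pv) <= 1e-8))
  expect_true(all(pv >= 0))

  # synthetic experiment: species silhouette on PC1-PC2 >= 0.5
  sim <- generate_count_experiment(features = 500, dispersion = 0.05,
                                   deg_fraction = 0.3, effect_size_log2 = 2,
                                   seed = 89)
  de_norm <- normalize_counts(sim$experiment)
  pc2 <- pca_profile(de_norm$normalized, sim$experiment$samples)
  xy <- as.matrix(pc2[, c("PC1", "PC2")])
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    same <- pc2$species == pc2$species[i]; same[i] <- FALSE
    a <- mean(d[i, same]); b <- mean(d[i, !same])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gte(mean(sil), 0.5)
})

test_that("full analysis wrapper produces coherent consensus output", {
  sim <- generate_count_experiment(features = 300, dispersion = 0.1,
                                   deg_fraction = 0.1, ddeg_fraction = 0.1,
                                   effect_size_log2 = 3,
                                   baseline_mean_log2 = c(8, 1),
                                   baseline_min = 50, seed = 90)
  de <- run_de_analysis(sim$experiment)
  expect_s3_class(de, "de_result")
  # padj >= p everywhere; calls imply padj <= alpha and |lfc| > 1
  expect_true(all(de$tests$padj >= de$tests$p, na.rm = TRUE))
  calls <- de$calls[de$calls$called, ]
  expect_true(all(calls$padj_lrt <= de$alpha & calls$padj_ql <= de$alpha))
  expect_true(all(abs(calls$log2fc_lrt) > de$lfc))
  # the strong planted DDEGs are found
  ddeg_called <- calls$feature_id[calls$test == "interaction"]
  expect_gt(length(intersect(ddeg_called,
                             sim$truth$feature_id[sim$truth$is_ddeg])), 0)
  # tidy/glance accessors
  expect_equal(nrow(glance(de)), 8)
  expect_true("called" %in% names(tidy(de)))
  expect_s3_class(plot_ma(de), "ggplot")
  expect_s3_class(plot_pca(pca_profile(de$normalized, de$experiment$samples)),
                  "ggplot")
})
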