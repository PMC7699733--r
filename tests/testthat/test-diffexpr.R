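test_that("design matrix keeps NA levels, flags collinearity by name", {
  meta <- toy_metadata(4, 4)
  X <- build_design(meta)
  expect_equal(nrow(X), 8)
  expect_equal(attr(X, "coef"), "cancer_statusYES")
  expect_equal(qr(X)$rank, ncol(X))

  meta$dup <- meta$cancer_status   # perfectly collinear covariate
  expect_error(build_design(meta, covariates = c("gender", "dup")),
               "rank deficient.*dup")
  expect_error(build_design(meta, group_var = "nope"), "no column")
})

test_that("with zero prior df the moderated t equals the OLS t", {
  sim <- simulate_cohort(sim_config(n_genes = 120, seed = 21))
  g <- collapse_to_genes(log_transform(sim$quant))
  de <- fit_moderated_model(g, sim$metadata, prior_df = 0)
  X <- build_design(sim$metadata)
  for (i in c(1, 7, 50, 120)) {
    fit <- lm(g$values[i, ] ~ X - 1)
    expect_equal(de$t[i], unname(summary(fit)$coefficients[2, 3]),
                 tolerance = 1e-8)
  }
})

test_that("moderated statistics match the closed-form posterior formula", {
  sim <- simulate_cohort(sim_config(n_genes = 150, seed = 22))
  g <- collapse_to_genes(log_transform(sim$quant))
  de <- fit_moderated_model(g, sim$metadata, min_detections = 0)
  d0 <- attr(de, "df_prior"); s02 <- attr(de, "s2_prior")
  d <- attr(de, "df_residual")

  # recompute the moderated t independently from the reported pieces
  de0 <- fit_moderated_model(g, sim$metadata, prior_df = 0)
  se_unscaled <- de0$log2fc / de0$t / sqrt(de0$sigma2)  # sqrt((X'X)^-1_jj)
  s2_post <- (d0 * s02 + d * de$sigma2) / (d0 + d)
  t_manual <- de$log2fc / (sqrt(s2_post) * se_unscaled)
  ok <- is.finite(t_manual)
  expect_gt(mean(ok), 0.95)
  expect_equal(de$t[ok], t_manual[ok], tolerance = 1e-8)
  expect_equal(de$p_value[ok],
               2 * pt(-abs(t_manual[ok]), df = d0 + d), tolerance = 1e-8)

  # coefficients and residual variances agree with the established fitter
  fit <- limma::lmFit(g$values, build_design(sim$metadata))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de$sigma2, unname(fit$sigma^2), tolerance = 1e-10)
})

test_that("null data give approximately uniform raw p values", {
  set.seed(77)
  vals <- matrix(abs(rnorm(1000 * 12, 20, 1)), 1000, 12)
  m <- toy_quant(vals)
  meta <- toy_metadata(6, 6)
  de <- fit_moderated_model(m, meta, covariates = character(0))
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("covariates orthogonal to the contrast leave the effect unchanged", {
  set.seed(31)
  vals <- matrix(abs(rnorm(50 * 8, 20, 1)), 50, 8)
  m <- toy_quant(vals)
  meta <- as_sample_metadata(data.frame(
    sample_id = sprintf("s%d", 1:8),
    cancer_status = rep(c("NO", "YES"), each = 4),
    gender = rep(c("F", "F", "M", "M"), 2),   # balanced within each group
    stringsAsFactors = FALSE))
  de0 <- fit_moderated_model(m, meta, covariates = character(0))
  de1 <- fit_moderated_model(m, meta, covariates = "gender")
  expect_equal(de0$log2fc, de1$log2fc, tolerance = 1e-10)
})

test_that("BH adjustment reproduces the step-up rule and validates input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  p <- runif(100)
  expect_true(all(adjust_bh(p) >= p))
  expect_true(all(adjust_bh(p) <= 1))
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("volcano table computes -log10 p and significance flags", {
  sim <- simulate_cohort(sim_config(n_genes = 80, seed = 12))
  de <- fit_moderated_model(log_transform(sim$quant), sim$metadata)
  v <- volcano_table(de)
  expect_equal(nrow(v), nrow(de))
  i <- which.min(abs(de$p_value - 0.05))
  expect_equal(v$neg_log10_p, -log10(de$p_value))
  expect_equal(round(-log10(0.05), 3), 1.301)
  expect_identical(v$significant_adjusted, de$adj_p_value < 0.05)
})
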