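test_that("min-max scaling maps rows to [0,1] with the constant-row rule", {
  m <- rbind(a = c(10, 20, 30), b = c(7, 7, 7))
  s <- scale_marker_matrix(m)
  expect_equal(unname(s["a", ]), c(0, 0.5, 1))
  expect_equal(unname(s["b", ]), c(0.5, 0.5, 0.5))

  set.seed(2)
  m2 <- matrix(runif(40), 10, 4)
  s2 <- scale_marker_matrix(m2)
  expect_true(all(apply(s2, 1, min) == 0))
  expect_true(all(apply(s2, 1, max) == 1))

  # rank variant uses mid-ranks
  s3 <- scale_marker_matrix(rbind(c(5, 1, 9)), method = "rank")
  expect_equal(unname(s3[1, ]), c(0.5, 0, 1))
  expect_error(scale_marker_matrix(matrix(1:3, 3, 1)), "at least 2")
})

test_that("purity scores average scaled values per flag class", {
  panel <- marker_panel(ev = c("CD63", "CD9"), non_ev = c("BCL2", "CANX"))
  scaled <- rbind(CD63 = c(1, 0), CD9 = c(1, 0),
                  BCL2 = c(0, 1), CANX = c(0, 1))
  colnames(scaled) <- c("clean", "dirty")
  rep <- purity_scores(scaled, panel)
  expect_equal(rep$ev_score, c(1, 0))
  expect_equal(rep$contamination_score, c(0, 1))

  # identical columns give identical scores
  scaled2 <- scaled; scaled2[, 2] <- scaled2[, 1]
  rep2 <- purity_scores(scaled2, panel)
  expect_equal(rep2$ev_score[1], rep2$ev_score[2])

  # a class with no marker present is undefined, unknown markers error
  rep3 <- purity_scores(scaled[c("CD63", "CD9"), ], panel)
  expect_true(all(is.na(rep3$contamination_score)))
  rownames(scaled)[1] <- "MYSTERY"
  expect_error(purity_scores(scaled, panel), "MYSTERY")
})

test_that("spiked contamination orders contamination scores", {
  sim <- simulate_cohort(sim_config(n_genes = 100, seed = 14))
  score_at <- function(level) {
    sp <- simulate_marker_panels(sim$quant, sim$metadata,
                                 contamination_level = level, seed = 14)
    lg <- log_transform(sp$quant)
    gm <- marker_group_means(lg, c(sp$panel$panels$EV,
                                   sp$panel$panels$`non-EV`))
    # compare against a zero-contamination reference column
    ref <- gm * 0
    rownames(ref) <- rownames(gm)
    ev_rows <- rownames(gm) %in% sp$panel$panels$EV
    ref[ev_rows, ] <- gm[ev_rows, ]
    scaled <- scale_marker_matrix(cbind(sample = rowMeans(gm),
                                        reference = rowMeans(ref)))
    purity_scores(scaled, sp$panel)$contamination_score[1]
  }
  expect_gt(score_at(22), score_at(0))
})

test_that("particle-to-protein ratio classification follows the thresholds", {
  expect_equal(as.character(classify_particle_protein_ratio(4e10, 1)), "high")
  expect_equal(as.character(classify_particle_protein_ratio(5e9, 1)), "low")
  expect_equal(as.character(classify_particle_protein_ratio(2.5e10, 1)),
               "indeterminate")
  expect_equal(as.character(classify_particle_protein_ratio(1e9, 1)),
               "below-low")
  # boundaries: 3e10 is not yet high; 2e9 and 2e10 are low
  expect_equal(as.character(classify_particle_protein_ratio(3e10, 1)),
               "indeterminate")
  expect_equal(as.character(classify_particle_protein_ratio(2e9, 1)), "low")
  expect_equal(as.character(classify_particle_protein_ratio(2e10, 1)), "low")
  expect_error(classify_particle_protein_ratio(1e10, 0), "positive")
  # total on r > 0: a spread of magnitudes never fails
  for (r in 10^seq(6, 12, 0.5))
    expect_true(as.character(classify_particle_protein_ratio(r, 1)) %in%
                  c("high", "indeterminate", "low", "below-low"))
})

test_that("NTA normalization sums to one and identical groups give p = 1", {
  d <- simulate_size_distributions(1, n_particles = 20000, seed = 30)[[1]]
  dists <- lapply(1:4, function(i) {
    x <- d; attr(x, "sample_id") <- paste0("s", i); x
  })
  nt <- nta_normalize_and_test(dists, c("A", "A", "B", "B"))
  expect_true(all(abs(colSums(nt$normalized) - 1) < 1e-9))
  informative <- !is.na(nt$per_bin$p_value)
  expect_true(all(nt$per_bin$t[informative] == 0))
  expect_true(all(nt$per_bin$p_value[informative] == 1))
  expect_true(all(nt$per_sample$modal_size == nt$per_sample$modal_size[1]))

  expect_error(nta_normalize_and_test(dists, c("A", "A", "A", "B")),
               "at least 2 samples")
  expect_error(nta_normalize_and_test(dists, c("A", "B", "C", "A")),
               "exactly two groups")
})

test_that("null NTA comparison keeps the per-bin false-positive rate near 5%", {
  fp <- vapply(1:20, function(s) {
    d <- simulate_size_distributions(24, n_particles = 50000, seed = s)
    nt <- nta_normalize_and_test(d, rep(c("A", "B"), each = 12))
    mean(nt$per_bin$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(fp), 0.02)
  expect_lt(mean(fp), 0.08)
})

test_that("min-max scaling keeps gene-wise ordering under single-column rescale", {
  set.seed(8)
  gm <- matrix(runif(60, 10, 100), 20, 3,
               dimnames = list(sprintf("m%d", 1:20), c("a", "b", "c")))
  s1 <- scale_marker_matrix(gm)
  gm2 <- gm; gm2[, "b"] <- gm2[, "b"] * 10
  s2 <- scale_marker_matrix(gm2)
  # rows where column b was neither min nor max keep their a/c ordering
  interior <- apply(gm, 1, function(r) which.min(r) != 2 & which.max(r) != 2)
  for (i in which(interior)) {
    expect_equal(order(s1[i, c("a", "c")]), order(s2[i, c("a", "c")]))
  }
})
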