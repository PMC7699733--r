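test_that("cohort generation is deterministic in the seed", {
  cfg <- sim_config(n_genes = 200, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$quant$values, b$quant$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(sim_config(n_genes = 200, seed = 43))
  expect_false(identical(a$quant$values, c$quant$values))
})

test_that("config validation rejects impossible cohorts", {
  expect_error(sim_config(n_control = 1, n_cancer = 0), "at least 2")
  expect_error(sim_config(n_de = -1), "must be >= 0")
  expect_error(sim_config(frac_stage4 = 1.2), "frac_stage4")
  expect_error(simulate_size_distributions(2, n_particles = 0),
               "n_particles")
  expect_error(simulate_size_distributions(2, mode_nm = -5), "mode_nm")
})

test_that("planted sample-unique proteins concentrate in poor-outcome samples", {
  top_rank <- vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(n_genes = 300, extra_unique_mean = 40,
                                      seed = s))
    counts <- unique_protein_counts(sim$quant)
    poor <- names(counts) %in% sim$truth$poor_outcome
    # every poor-outcome sample should out-rank every other sample
    min(counts[poor]) > max(counts[!poor])
  }, logical(1))
  expect_gte(mean(top_rank), 0.9)
})

test_that("no planted excess means no group dependence of unique counts", {
  sim <- simulate_cohort(sim_config(n_genes = 300, extra_unique_mean = 0,
                                    seed = 9))
  expect_length(unlist(sim$truth$unique_proteins), 0)
  expect_false(any(grepl("^UNIQ-", sim$quant$protein_ids)))
})

test_that("marginal detection rate rises with mean abundance", {
  rates <- vapply(c(19, 22, 25), function(mu) {
    sim <- simulate_cohort(sim_config(n_genes = 400, mu_log2 = mu, n_de = 0,
                                      seed = 5))
    mean(sim$quant$values > 0)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("marker spiking honours contamination level and planted shifts", {
  sim <- simulate_cohort(sim_config(n_genes = 100, seed = 3))
  sp0 <- simulate_marker_panels(sim$quant, sim$metadata,
                                contamination_level = 0, seed = 3)
  nonev <- sp0$panel$panels$`non-EV`
  expect_true(all(sp0$quant$values[nonev, ] == 0))

  # constant spike, no noise: population score equals the spiked level
  spc <- simulate_marker_panels(sim$quant, sim$metadata, pop_level = 24,
                                noise_sd = 0, seed = 3)
  lg <- log_transform(spc$quant)
  ps <- population_scores(lg, spc$panel)
  expect_equal(unname(ps$scores["T cells", ]),
               rep(log2(2^24 + 1), 24), tolerance = 1e-10)

  # monotone planted shift at zero noise: every cancer sample above every
  # control sample for the shifted population
  sps <- simulate_marker_panels(sim$quant, sim$metadata, noise_sd = 0,
                                pop_shift = list("Monocytic lineage" = 2),
                                seed = 3)
  ps <- population_scores(log_transform(sps$quant), sps$panel)
  grp <- sim$metadata$cancer_status[match(colnames(ps$scores),
                                          sim$metadata$sample_id)]
  mono <- ps$scores["Monocytic lineage", ]
  expect_true(min(mono[grp == "YES"]) > max(mono[grp == "NO"]))
})

test_that("size distribution generator hits the requested mode and is seeded", {
  a <- simulate_size_distributions(2, seed = 11)
  b <- simulate_size_distributions(2, seed = 11)
  expect_identical(a[[1]]$count, b[[1]]$count)

  # analytic mode of the binned expected distribution within one bin of the
  # requested 100 nm
  edges <- seq(40, 400, by = 0.5)
  meanlog <- log(100) + 0.35^2
  mass <- plnorm(edges[-1], meanlog, 0.35) -
    plnorm(edges[-length(edges)], meanlog, 0.35)
  expect_lte(abs(edges[which.max(mass)] - 100), 1)

  # empirical mode lands near 100 nm at realistic particle counts
  d <- simulate_size_distributions(1, n_particles = 2e5, seed = 2)[[1]]
  expect_lt(abs(d$size[which.max(d$count)] - 100), 15)
})

test_that("synthetic gene sets cover a universe larger than the proteome", {
  sets <- simulate_gene_sets(sprintf("G%03d", 1:100), n_background = 12,
                             set_size = 10, planted_members = c("G001", "G002"),
                             seed = 1)
  expect_length(sets, 13)
  expect_true("PLANTED" %in% names(sets))
  members <- unlist(sets[names(sets) != "PLANTED"], use.names = FALSE)
  expect_true(any(grepl("^ANNOT", members)))
})
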