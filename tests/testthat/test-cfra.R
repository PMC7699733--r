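test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("G%02d", 1:10)
  sets <- list(cat = universe[1:5])
  res <- hypergeom_enrichment(universe[1:4], universe, sets)
  expect_equal(res$k, 4L)
  expect_equal(res$p_value, 5 / 210)  # C(10,4) draws, 5 contain all 4 hits

  # query = universe: every category fully covered, P(X >= K) = 1
  res2 <- hypergeom_enrichment(universe, universe,
                               list(a = universe[1:3], b = universe[4:10]))
  expect_true(all(res2$p_value == 1))

  # zero overlap: p = P(X >= 0) = 1
  res3 <- hypergeom_enrichment(universe[1:2], universe,
                               list(a = universe[5:8]))
  expect_equal(res3$p_value, 1)

  expect_error(hypergeom_enrichment("X", universe, sets), "outside")
  expect_error(hypergeom_enrichment("G01", character(), sets), "empty")
})

test_that("hypergeometric p equals subset enumeration for N <= 15", {
  set.seed(55)
  for (rep in 1:20) {
    N <- sample(5:15, 1)
    universe <- sprintf("U%02d", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    sets <- list(s = sample(universe, K))
    query <- sample(universe, n)
    got <- hypergeom_enrichment(query, universe, sets)
    k <- length(intersect(sets$s, query))
    expect_equal(got$p_value, brute_hyper_p(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("category regulation applies the joint three-filter rule", {
  # 30 identified genes; category members strongly up (mean 1.3, FC 2.46),
  # universe padded with unmeasured annotation so enrichment can fire
  set.seed(60)
  identified <- sprintf("G%02d", 1:30)
  universe <- c(identified, sprintf("A%02d", 1:30))
  ratios <- stats::setNames(rnorm(30, 0, 0.05), identified)
  members <- identified[1:6]
  ratios[members] <- c(1.3, 1.4, 1.2, 1.35, 1.25, 1.3)
  sets <- list(up_cat = members,
               null_cat = c(identified[10:15], sprintf("A%02d", 1:6)))
  res <- category_regulation(ratios, sets, universe = universe)
  up <- res[res$category == "up_cat", ]
  expect_equal(up$direction, "up")
  expect_gt(up$fold_change, 2)
  expect_lt(up$p_enrichment, 0.05)
  expect_equal(up$stars_regulation, "***")
  expect_equal(res$direction[res$category == "null_cat"], "unregulated")

  # FC 1.8 with both p significant still fails the two-fold filter
  ratios2 <- stats::setNames(rep(log2(1.8), 6), members)
  res2 <- suppressMessages(
    category_regulation(ratios2, list(cat = members),
                        universe = c(members, sprintf("A%02d", 1:20))))
  expect_equal(res2$direction, "unregulated")
  expect_lt(res2$p_enrichment, 0.05)

  # all-zero ratios: FC = 1, unregulated
  res3 <- category_regulation(stats::setNames(rep(0, 6), members),
                              list(cat = members))
  expect_equal(res3$fold_change, 1)
  expect_equal(res3$direction, "unregulated")

  # infinite fold-change threshold suppresses every call
  res4 <- category_regulation(ratios, sets, universe = universe,
                              fc_threshold = Inf)
  expect_true(all(res4$direction == "unregulated"))

  # member order and duplicated annotation entries are irrelevant
  res5 <- category_regulation(ratios, list(up_cat = rev(c(members, members))),
                              universe = universe)
  expect_equal(res5$direction, up$direction)
  expect_equal(res5$p_regulation, up$p_regulation)

  # categories below the member floor are excluded with a message
  expect_message(
    small <- category_regulation(ratios, list(tiny = members[1]),
                                 universe = universe),
    "excluded")
  expect_equal(nrow(small), 0)
})

test_that("cross-comparison table keeps categories regulated anywhere", {
  one <- data.frame(category = "catA", n_identified = 5L, n_annotated = 8L,
                    mean_log2_ratio = 1.5, fold_change = 2.8,
                    p_regulation = 0.001, p_enrichment = 0.01,
                    direction = "up", adj_p_regulation = 0.001,
                    adj_p_enrichment = 0.01, stars_regulation = "***",
                    stars_enrichment = "*", stringsAsFactors = FALSE)
  none <- one; none$direction <- "unregulated"; none$category <- "catB"
  tab <- cfra_matrix(list(A = structure(one, class = c("cfra_result",
                                                       "data.frame")),
                          B = structure(none, class = c("cfra_result",
                                                        "data.frame"))))
  expect_equal(nrow(tab), 2)              # catA x {A, B}
  expect_equal(tab$direction[tab$comparison == "A"], "up")
  # absent from comparison B -> rendered unregulated with NA counts
  expect_equal(tab$direction[tab$comparison == "B"], "unregulated")
  expect_true(is.na(tab$n_identified[tab$comparison == "B"]))

  # no regulated category anywhere -> empty table, not an error
  empty <- cfra_matrix(list(A = structure(none,
                                          class = c("cfra_result",
                                                    "data.frame"))))
  expect_equal(nrow(empty), 0)
  expect_error(cfra_matrix(list()), "no comparisons")
})

test_that("planted category regulation is recovered from simulated cohorts", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_cohort(sim_config(n_genes = 800, n_de = 60,
                                      de_log2fc = 1.5, seed = s))
    planted <- names(sim$truth$de_direction[sim$truth$de_direction > 0])
    pp <- preprocess(sim$quant, "log_quantile")
    ratios <- group_log_ratios(pp$quant, sim$metadata)
    sets <- simulate_gene_sets(unique(sim$quant$gene_symbols),
                               n_background = 20,
                               planted_members = planted, seed = s)
    cf <- suppressMessages(category_regulation(ratios, sets))
    c(cf$direction[cf$category == "PLANTED"] == "up")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
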