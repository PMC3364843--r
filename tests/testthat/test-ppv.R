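test_that("partitions are balanced, disjoint and deterministic", {
  ph <- binary_pheno(50, 50)
  ps <- make_partitions(ph, n_partitions = 20, seed = 3)
  y <- unclass(ph)
  for (pr in ps$partitions) {
    expect_length(intersect(pr$train, pr$test), 0)
    expect_equal(length(pr$train), length(pr$test))
    expect_equal(sum(y[pr$train]), 25)          # 25 per class each half
    expect_equal(sum(y[pr$test] == 0), 25)
  }
  ps2 <- make_partitions(ph, n_partitions = 20, seed = 3)
  expect_identical(ps, ps2)
  expect_false(identical(ps, make_partitions(ph, 20, seed = 4)))
})

test_that("odd strata drop one surplus sample per partition", {
  ph <- binary_pheno(11, 9)
  ps <- make_partitions(ph, n_partitions = 10, seed = 5)
  y <- unclass(ph)
  for (pr in ps$partitions) {
    used <- c(pr$train, pr$test)
    expect_equal(length(used), 18)              # one dropped per class
    expect_equal(sum(y[pr$train]), 4)
    expect_equal(sum(y[pr$train] == 0), 5)
  }
  expect_error(make_partitions(binary_pheno(1, 5), 5, 1), "stratum")
})

test_that("continuous partitions balance the phenotype distribution", {
  set.seed(6)
  ph <- continuous_pheno(runif(80, 25, 90))
  ps <- make_partitions(ph, n_partitions = 10, seed = 7)
  y <- unclass(ph)
  for (pr in ps$partitions) {
    expect_equal(length(pr$train), length(pr$test))
    expect_lt(abs(median(y[pr$train]) - median(y[pr$test])), 15)
  }
})

test_that("random half-splits have the expected pairwise train overlap", {
  ph <- binary_pheno(30, 30)
  ps <- make_partitions(ph, n_partitions = 50, seed = 11)
  trains <- lapply(ps$partitions, `[[`, "train")
  jac <- combn(50, 2, function(ij) {
    a <- trains[[ij[1]]]; b <- trains[[ij[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  expect_lt(abs(mean(jac) - 1 / 3), 0.05)
})

test_that("true positives require both significance and direction concordance", {
  train <- manual_ranked(paste0("cg", 1:50), direction = rep(1, 50))
  # all significant and concordant
  good <- manual_assoc(paste0("cg", 1:50), p = rep(0.001, 50),
                       direction = rep(1, 50))
  expect_equal(count_true_positives(train, good, 50), 50)
  # nothing significant
  bad <- manual_assoc(paste0("cg", 1:50), p = rep(1, 50),
                      direction = rep(1, 50))
  expect_equal(count_true_positives(train, bad, 50), 0)
  # 3 of 50: two significant+concordant among top, one more further down,
  # one significant but discordant is excluded
  p <- rep(0.5, 50); dir <- rep(1, 50)
  p[c(3, 17, 41)] <- 0.01
  p[8] <- 0.001; dir[8] <- -1
  mixed <- manual_assoc(paste0("cg", 1:50), p = p, direction = dir)
  expect_equal(count_true_positives(train, mixed, 50), 3)
  # CpGs missing from the test table count as not positive
  short <- manual_assoc(paste0("cg", 1:40), p = rep(0.001, 40),
                        direction = rep(1, 40))
  expect_equal(count_true_positives(train, short, 50), 40)
  expect_equal(count_true_positives(train, good, 0), 0)
})

test_that("PPV curves are bounded, deterministic and perfect under an oracle", {
  sim <- simulate_beta_matrix(sim_config(n_features = 800, n_per_group = 30,
                                         n_true = 200,
                                         target_effect_size = 3, seed = 21))
  ps <- make_partitions(sim$phenotype, n_partitions = 5, seed = 22)
  pv <- ppv_curve(sim$matrix, sim$phenotype, ps, method = "WF",
                  statistic = "t", sizes = c(50, 100, 150), k = 200)
  expect_true(all(pv >= 0 & pv <= 1))
  pv2 <- ppv_curve(sim$matrix, sim$phenotype, ps, method = "WF",
                   statistic = "t", sizes = c(50, 100, 150), k = 200)
  expect_identical(unclass(pv), unclass(pv2))
  # strong signal: top-50 selections validate almost perfectly
  expect_gt(mean_ppv(pv)[1], 0.95)
})

test_that("sizes beyond the selected list are flagged and scored on the full list", {
  sim <- simulate_beta_matrix(sim_config(n_features = 300, n_per_group = 20,
                                         n_true = 30, target_effect_size = 2.5,
                                         seed = 23))
  ps <- make_partitions(sim$phenotype, n_partitions = 3, seed = 24)
  pv <- suppressMessages(ppv_curve(sim$matrix, sim$phenotype, ps,
                                   method = "VF", statistic = "t",
                                   sizes = c(10, 250), k = 50))
  tr <- attr(pv, "truncated")
  expect_false(any(tr[1, ]))
  expect_true(all(tr[2, ]))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("oracle truth capture tracks the test-set PPV across partitions", {
  sim <- simulate_beta_matrix(sim_config(n_features = 2000,
                                         n_per_group = 30, n_true = 150,
                                         target_effect_size = 1.2,
                                         seed = 25))
  ps <- make_partitions(sim$phenotype, n_partitions = 12, seed = 26)
  xm <- unclass(sim$matrix)
  truth <- sim$truth$true_feature_ids
  ppv <- numeric(0); oracle <- numeric(0)
  for (pr in ps$partitions) {
    ptr <- phenotype(unclass(sim$phenotype)[pr$train], "binary")
    pte <- phenotype(unclass(sim$phenotype)[pr$test], "binary")
    sel <- select_wf(t_test_by_feature(xm[, pr$train], ptr), k = 150)
    ta <- t_test_by_feature(xm[, pr$test], pte)
    ppv <- c(ppv, count_true_positives(sel, ta, 150) / 150)
    oracle <- c(oracle, mean(sel$cpg %in% truth))
  }
  expect_gt(cor(ppv, oracle), 0)
})

test_that("small-sample evaluation validates its inputs and is reproducible", {
  sim <- simulate_beta_matrix(sim_config(n_features = 500, n_per_group = 10,
                                         n_true = 100,
                                         target_effect_size = 2.5,
                                         seed = 27))
  pv <- small_sample_ppv(sim$matrix, sim$phenotype, n_per_class = 2,
                         sizes = c(20, 50), k = 100, n_partitions = 5,
                         seed = 28)
  expect_identical(attr(pv, "statistic"), "moderated_t")
  expect_true(all(pv >= 0 & pv <= 1))
  pv2 <- small_sample_ppv(sim$matrix, sim$phenotype, n_per_class = 2,
                          sizes = c(20, 50), k = 100, n_partitions = 5,
                          seed = 28)
  expect_identical(unclass(pv), unclass(pv2))
  expect_error(small_sample_ppv(sim$matrix, sim$phenotype, n_per_class = 6),
               "disjoint")
})

test_that("Wilcoxon comparison matches exact enumeration", {
  cmp <- compare_ppv(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(cmp$p_value, 0.1)                     # 2/20 rank assignments
  expect_equal(cmp$median_a, 0.2)
  same <- compare_ppv(rep(0.5, 10), rep(0.5, 10))
  expect_equal(same$p_value, 1)
  set.seed(29)
  a <- runif(50); b <- a + 0.5
  expect_lt(compare_ppv(a, b)$p_value, 1e-8)
  expect_lt(compare_ppv(a, b, alternative = "less")$p_value, 1e-8)
})

test_that("evaluation sizes are chosen to equalize PPV across studies", {
  grid <- seq(50, 500, by = 50)
  flat <- stats::setNames(rep(0.9, 10), grid)
  decr <- stats::setNames(seq(0.95, 0.85, length.out = 10), grid)
  pick <- choose_evaluation_sizes(list(A = flat, B = decr))
  expect_equal(unname(pick["B"]), grid[which.min(abs(decr - 0.9))])
  # identical curves: tie rule drives both to the smallest size
  pick2 <- choose_evaluation_sizes(list(A = decr, B = decr))
  expect_equal(unname(pick2), c(50, 50))
  # forced single size
  pick3 <- choose_evaluation_sizes(list(A = flat, B = decr),
                                   min_size = 200, max_size = 200)
  expect_equal(unname(pick3), c(200, 200))
  expect_error(choose_evaluation_sizes(list(A = flat, B = decr),
                                       min_size = 1000), "feasible")
})
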