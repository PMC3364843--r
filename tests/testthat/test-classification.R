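test_that("C-index matches pair enumeration and its boundary cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(evaluate_cindex(c(1, 2, 4, 3), y)$c_index, 5 / 6)
  expect_equal(evaluate_cindex(y, y)$c_index, 1)
  expect_equal(evaluate_cindex(-y, y)$c_index, 0)
  expect_equal(evaluate_cindex(rep(1, 4), y)$c_index, 0.5)   # all ties
  expect_equal(evaluate_cindex(c(1, 2, 4, 3), y)$n_comparable_pairs, 6)
  expect_error(evaluate_cindex(c(1, 2), c(3, 3)), "comparable")
  # reversing the predictor reflects the index around 1/2
  set.seed(1)
  p <- rnorm(30); yy <- rnorm(30)
  expect_equal(evaluate_cindex(-p, yy)$c_index,
               1 - evaluate_cindex(p, yy)$c_index)
})

test_that("C-index is invariant under strictly increasing transforms", {
  set.seed(2)
  p <- rnorm(40); y <- rnorm(40)
  base <- evaluate_cindex(p, y)$c_index
  expect_equal(evaluate_cindex(exp(p), y)$c_index, base)
  expect_equal(evaluate_cindex(rank(p), y)$c_index, base)
})

test_that("C-index agrees with the survival package concordance", {
  skip_if_not_installed("survival")
  set.seed(3)
  p <- rnorm(50); y <- rnorm(50)
  ours <- evaluate_cindex(p, y)$c_index
  ref <- survival::concordance(y ~ p)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("elastic net returns the null model at lambda >= lambda_max", {
  set.seed(4)
  n <- 60
  x <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(paste0("cg", 1:30), paste0("S", 1:n)))
  y <- continuous_pheno(x[1, ] + rnorm(n, 0, 0.5), ids = colnames(x))
  xs <- t(scale(t(x)))
  lmax <- max(abs(xs %*% (unclass(y) - mean(y)))) / n
  fit <- fit_elastic_net(x, y, alpha = 1, n_filter = NULL,
                         lambda = lmax * 1.05)
  cf <- as.numeric(glmnet::coef.glmnet(fit$fit, s = fit$lambda))[-1]
  expect_true(all(cf == 0))
})

test_that("univariate lasso solution equals the soft-thresholded OLS slope", {
  set.seed(5)
  n <- 4000
  x1 <- as.numeric(scale(rnorm(n))) * sqrt(n / (n - 1))   # exact unit 1/n-sd
  x2 <- as.numeric(scale(rnorm(n))) * sqrt(n / (n - 1))   # independent dummy
  x <- rbind(cg1 = x1, cg2 = x2)
  colnames(x) <- paste0("S", 1:n)
  y <- continuous_pheno(0.5 * x1 + rnorm(n), ids = colnames(x))
  b <- mean(x1 * (unclass(y) - mean(y)))                  # OLS slope
  for (lam in c(0.05, 0.2)) {
    fit <- fit_elastic_net(x, y, alpha = 1, n_filter = NULL, lambda = lam)
    cf <- as.numeric(glmnet::coef.glmnet(fit$fit, s = lam))[-1]
    expect_equal(cf[1], sign(b) * max(abs(b) - lam, 0), tolerance = 5e-3)
  }
})

test_that("the elastic net spreads weight over correlated truth features", {
  set.seed(6)
  n <- 80
  f <- rnorm(n)
  truth <- t(sapply(1:50, function(i) f + rnorm(n, 0, 0.8)))
  nulls <- matrix(rnorm(150 * n), 150, n)
  x <- rbind(truth, nulls)
  rownames(x) <- c(paste0("cgT", 1:50), paste0("cgN", 1:150))
  colnames(x) <- paste0("S", 1:n)
  y <- continuous_pheno(f + rnorm(n, 0, 0.3), ids = colnames(x))
  nz <- function(alpha) {
    fit <- fit_elastic_net(x, y, alpha = alpha, n_filter = NULL, seed = 7)
    cf <- as.numeric(glmnet::coef.glmnet(fit$fit, s = fit$lambda))[-1]
    sum(cf != 0 & startsWith(rownames(x), "cgT"))
  }
  expect_gt(nz(0.05), nz(1))
})

test_that("elastic net predictions track the phenotype on signal data", {
  set.seed(7)
  sim <- simulate_beta_matrix(sim_config(n_features = 1000,
                                         n_per_group = 80,
                                         phenotype_type = "continuous",
                                         n_true = 100,
                                         target_effect_size = 1.5,
                                         seed = 8))
  x <- unclass(sim$matrix)
  tr <- paste0("S", 1:60); te <- paste0("S", 61:80)
  ptr <- phenotype(unclass(sim$phenotype)[tr], "continuous")
  fit <- fit_elastic_net(x[, tr], ptr, alpha = 0.05, seed = 9)
  pred <- predict(fit, x[, te])
  yte <- unclass(sim$phenotype)[te]
  expect_gt(evaluate_cindex(pred, yte)$c_index, 0.8)
  expect_error(fit_elastic_net(x[, tr],
                               phenotype(stats::setNames(rep(1, 60), tr),
                                         "continuous")), "constant")
})

test_that("SPCA predictor recovers a planted one-factor phenotype", {
  set.seed(10)
  n <- 60
  f <- runif(n, 25, 90)
  loadings <- rnorm(300, 0, 0.002)
  loadings[1:80] <- rnorm(80, 0, 0.01) + 0.01
  x <- 0.5 + outer(loadings, as.numeric(scale(f))) +
    matrix(rnorm(300 * n, 0, 0.02), 300, n)
  rownames(x) <- paste0("cg", sprintf("%03d", 1:300))
  colnames(x) <- paste0("S", 1:n)
  tr <- colnames(x)[1:40]; te <- colnames(x)[41:60]
  ptr <- continuous_pheno(f[1:40], ids = tr)
  m1 <- fit_spca_predictor(x[, tr], ptr, n_components = 1,
                           max_features = 200, seed = 11)
  p1 <- predict(m1, x[, te])
  c1 <- evaluate_cindex(p1, f[41:60])$c_index
  expect_gt(c1, 0.9)
  # extra components add no signal on a one-factor fixture
  m3 <- fit_spca_predictor(x[, tr], ptr, n_components = 3,
                           max_features = 200, seed = 11)
  c3 <- evaluate_cindex(predict(m3, x[, te]), f[41:60])$c_index
  expect_lte(c3, c1 + 0.02)
  # fixed seed: identical chosen threshold and predictions
  m1b <- fit_spca_predictor(x[, tr], ptr, n_components = 1,
                            max_features = 200, seed = 11)
  expect_identical(m1$threshold, m1b$threshold)
  expect_equal(p1, predict(m1b, x[, te]))
  expect_error(fit_spca_predictor(x[, tr], ptr, n_components = 50,
                                  seed = 1), "n_components")
})

test_that("SVM regression learns a monotone single-feature relationship", {
  set.seed(12)
  n <- 80
  f <- runif(n, 25, 90)
  x <- matrix(0.2 + 0.006 * f + rnorm(n, 0, 0.02), 1, n,
              dimnames = list("cg1", paste0("S", 1:n)))
  tr <- colnames(x)[1:60]; te <- colnames(x)[61:80]
  fit <- fit_svm_regression(x[, tr, drop = FALSE],
                            continuous_pheno(f[1:60], ids = tr))
  pred <- predict(fit, x[, te, drop = FALSE])
  expect_gt(evaluate_cindex(pred, f[61:80])$c_index, 0.9)
  # reordering the training samples leaves the predictor unchanged
  perm <- sample(tr)
  fit2 <- fit_svm_regression(x[, perm, drop = FALSE],
                             continuous_pheno(f[match(perm, colnames(x))],
                                              ids = perm))
  expect_equal(unname(predict(fit2, x[, te, drop = FALSE])), unname(pred),
               tolerance = 1e-3)
})

test_that("training predictions respect the epsilon tube for non-support points", {
  set.seed(13)
  n <- 50
  f <- runif(n, 25, 90)
  x <- rbind(scale_row <- 0.2 + 0.006 * f + rnorm(n, 0, 0.01))
  rownames(x) <- "cg1"; colnames(x) <- paste0("S", 1:n)
  ph <- continuous_pheno(as.numeric(scale(f)), ids = colnames(x))
  fit <- fit_svm_regression(x, ph)
  pred <- predict(fit, x)
  off_sv <- setdiff(seq_len(n), fit$fit$index)   # non-support points
  expect_gt(length(off_sv), 0)
  expect_true(all(abs(pred[off_sv] - unclass(ph)[off_sv]) <= 0.1 + 1e-6))
})

test_that("classifier comparison reports coherent medians on null data", {
  sim <- simulate_beta_matrix(sim_config(n_features = 300,
                                         n_per_group = 60,
                                         phenotype_type = "continuous",
                                         n_true = 0, seed = 14))
  ps <- make_partitions(sim$phenotype, n_partitions = 4, seed = 15)
  cmp <- run_classifier_comparison(sim$matrix, sim$phenotype, ps, seed = 16,
                                   methods = c("SPCA-1", "LASSO", "ELNET",
                                               "SVM"))
  sm <- summarize_comparison(cmp)
  expect_true(all(abs(sm$medians - 0.5) < 0.15))
  expect_true(all(cmp$c_index >= 0 & cmp$c_index <= 1))
  cmp2 <- run_classifier_comparison(sim$matrix, sim$phenotype, ps, seed = 16,
                                    methods = c("SPCA-1", "LASSO", "ELNET",
                                                "SVM"))
  expect_identical(cmp, cmp2)
})
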