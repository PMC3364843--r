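#' Concordance index for continuous outcomes
#'
#' Over all sample pairs with distinct phenotype values, counts a pair
#' concordant when the predictions are ordered like the phenotypes;
#' prediction ties contribute one half. The C-index is
#' `(concordant + 0.5 * ties) / comparable` and equals 0.5 for an
#' uninformative predictor, 1 for a perfect one and 0 for a perfectly
#' reversed one. It is invariant under strictly increasing transforms of
#' the predictions.
#'
#' @param predictions Numeric predictor scores.
#' @param y Continuous outcome (numeric or [phenotype()]), same length.
#' @return List of class `concordance_result` with `c_index` and
#'   `n_comparable_pairs`.
#' @export
evaluate_cindex <- function(predictions, y) {
  y <- if (inherits(y, "phenotype")) pheno_values(y) else as.numeric(y)
  predictions <- as.numeric(predictions)
  n <- length(y)
  stopifnot(length(predictions) == n, n >= 2)
  dy <- outer(y, y, "-")
  dp <- outer(predictions, predictions, "-")
  up <- upper.tri(dy) & dy != 0
  comparable <- sum(up)
  if (comparable == 0L) stop("all phenotype values equal: no comparable pairs")
  conc <- sum(dp[up] * dy[up] > 0)
  ties <- sum(dp[up] == 0)
  structure(list(c_index = (conc + 0.5 * ties) / comparable,
                 n_comparable_pairs = comparable),
            class = "concordance_result")
}

# rank features on the training half for predictor pre-filters
.univariate_rank <- function(xm, y_num) {
  ph <- phenotype(stats::setNames(y_num, colnames(xm)), "continuous")
  assoc <- linear_assoc(xm, ph)
  .assoc_order(assoc)
}

#' Supervised principal components predictor
#'
#' Builds a continuous-phenotype predictor from the leading principal
#' components of the most phenotype-associated CpGs. Per-feature
#' univariate regression statistics rank the CpGs; a log-spaced grid of
#' feature-count thresholds between `min_features` and `max_features` is
#' scored by internal 10-fold cross-validation (ranking, SVD and
#' regression refit inside every fold; pooled out-of-fold predictions
#' scored by C-index), and the best threshold is kept. The final model is
#' an SVD of the top-threshold training submatrix with the phenotype
#' regressed on the first `n_components` component scores; test samples
#' are projected onto the stored loadings.
#'
#' @param x Training [methyl_matrix()] or numeric matrix (CpGs x samples).
#' @param ph Continuous training [phenotype()].
#' @param n_components Number of principal components (1 to 3 typical).
#' @param min_features,max_features Bounds of the threshold grid.
#' @param n_thresholds Grid resolution.
#' @param nfolds Internal CV folds.
#' @param seed Seed for the fold assignment.
#' @return A `methyl_predictor` (method `"SPCA"`) usable with `predict`.
#' @export
fit_spca_predictor <- function(x, ph, n_components = 1,
                               min_features = 10, max_features = 5000,
                               n_thresholds = 7, nfolds = 10, seed = 1) {
  fits <- .spca_cv(x, ph, max(n_components), min_features, max_features,
                   n_thresholds, nfolds, seed)
  fits[[n_components]]
}

# Shared CV pass returning one fitted model per component count
# 1..n_components (the SVD per threshold/fold is reused across component
# counts, which is what makes the three SPCA variants cheap to compare).
.spca_cv <- function(x, ph, n_components, min_features, max_features,
                     n_thresholds, nfolds, seed) {
  stopifnot(inherits(ph, "phenotype"))
  if (phenotype_type(ph) != "continuous") {
    stop("SPCA predictor requires a continuous phenotype")
  }
  xm <- unwrap(x)
  y <- pheno_values(ph)
  n <- length(y)
  if (ncol(xm) != n) stop("matrix and phenotype sizes differ")
  if (n_components > min(n - 1L, nrow(xm))) {
    stop("n_components exceeds what the training data can support")
  }
  max_features <- min(max_features, nrow(xm))
  min_features <- min(min_features, max_features)
  grid <- unique(round(exp(seq(log(min_features), log(max_features),
                               length.out = n_thresholds))))
  foldid <- stratified_folds(y, nfolds, seed = seed)
  nf <- max(foldid)
  cvpred <- array(NA_real_, c(n, length(grid), n_components))
  for (f in seq_len(nf)) {
    tr <- which(foldid != f); te <- which(foldid == f)
    if (length(tr) <= n_components + 1L) next
    ord <- .univariate_rank(xm[, tr, drop = FALSE], y[tr])
    for (g in seq_along(grid)) {
      m <- min(grid[g], length(ord))
      feats <- ord[seq_len(m)]
      sub <- xm[feats, tr, drop = FALSE]
      ctr <- rowMeans(sub)
      sub <- sub - ctr
      k <- min(n_components, length(tr) - 1L, m)
      sv <- svd(sub, nu = k, nv = k)
      scr <- sv$v * rep(sv$d[seq_len(k)], each = nrow(sv$v))
      proj <- crossprod(xm[feats, te, drop = FALSE] - ctr, sv$u)
      for (kk in seq_len(n_components)) {
        ku <- min(kk, k)
        cf <- stats::lm.fit(cbind(1, scr[, seq_len(ku), drop = FALSE]),
                            y[tr])$coefficients
        cf[is.na(cf)] <- 0
        cvpred[te, g, kk] <- cbind(1, proj[, seq_len(ku), drop = FALSE]) %*% cf
      }
    }
  }
  lapply(seq_len(n_components), function(kk) {
    cvc <- vapply(seq_along(grid), function(g) {
      okk <- !is.na(cvpred[, g, kk])
      if (sum(okk) < 2L) return(NA_real_)
      evaluate_cindex(cvpred[okk, g, kk], y[okk])$c_index
    }, numeric(1))
    g_best <- which.max(cvc)           # first maximum: smaller threshold
    m <- grid[g_best]
    ord <- .univariate_rank(xm, y)
    feats <- rownames(xm)[ord[seq_len(min(m, length(ord)))]]
    sub <- xm[feats, , drop = FALSE]
    ctr <- rowMeans(sub)
    sub <- sub - ctr
    k <- min(kk, n - 1L, length(feats))
    sv <- svd(sub, nu = k, nv = k)
    scr <- sv$v * rep(sv$d[seq_len(k)], each = nrow(sv$v))
    cf <- stats::lm.fit(cbind(1, scr), y)$coefficients
    cf[is.na(cf)] <- 0
    structure(list(method = "SPCA", n_components = kk,
                   features = feats, center = ctr, loadings = sv$u,
                   coef = cf, threshold = m, cv_cindex = cvc,
                   threshold_grid = grid),
              class = "methyl_predictor")
  })
}

#' Elastic-net / LASSO predictor
#'
#' Penalized linear regression of the phenotype on the (by default)
#' 5,000 most variable training CpGs, with internally standardized
#' features, solved over a decreasing lambda path; lambda is chosen by
#' internal 10-fold cross-validation (minimum mean squared error). The
#' LASSO is the special case `alpha = 1`; the elastic-net default is
#' `alpha = 0.05`, whose heavy ridge component spreads weight over groups
#' of correlated CpGs.
#'
#' @inheritParams fit_spca_predictor
#' @param alpha Elastic-net mixing parameter in `(0, 1]`.
#' @param n_filter Keep this many top-variance training features before
#'   fitting (`NULL` to use all).
#' @param lambda Optional fixed lambda (skips cross-validation).
#' @param nfolds Internal CV folds.
#' @return A `methyl_predictor` (method `"ELNET"`).
#' @export
fit_elastic_net <- function(x, ph, alpha = 0.05, n_filter = 5000,
                            lambda = NULL, nfolds = 10, seed = 1) {
  stopifnot(alpha > 0, alpha <= 1, inherits(ph, "phenotype"))
  xm <- unwrap(x)
  y <- pheno_values(ph)
  if (stats::var(y) == 0) stop("phenotype is constant")
  if (!is.null(n_filter) && nrow(xm) > n_filter) {
    keep <- order(-row_vars(xm), rownames(xm))[seq_len(n_filter)]
    xm <- xm[keep, , drop = FALSE]
  }
  xt <- t(xm)
  if (is.null(lambda)) {
    nfolds <- max(3L, min(nfolds, length(y) %/% 4L))  # >= 4 obs per fold
    foldid <- stratified_folds(y, nfolds, seed = seed)
    cv <- glmnet::cv.glmnet(xt, y, alpha = alpha, foldid = foldid,
                            standardize = TRUE, family = "gaussian",
                            lambda.min.ratio = 1e-3, nlambda = 100)
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
  } else {
    # solve along a path that terminates exactly at the requested lambda,
    # so no interpolation is needed when extracting the solution
    n <- length(y)
    ysc <- y - mean(y)
    xsd <- sqrt(row_vars(xm) * (n - 1) / n)
    ok <- xsd > 0
    lmax <- max(abs(((xm[ok, , drop = FALSE] - rowMeans(xm)[ok]) / xsd[ok]) %*%
                      ysc)) / (n * alpha)
    top <- max(lmax * 1.05, lambda * 1.001)
    path <- exp(seq(log(top), log(lambda), length.out = 60))
    path[length(path)] <- lambda    # exact terminal knot
    path <- unique(path)
    fit <- glmnet::glmnet(xt, y, alpha = alpha, standardize = TRUE,
                          family = "gaussian", lambda = path)
  }
  structure(list(method = "ELNET", fit = fit, lambda = lambda,
                 alpha = alpha, features = rownames(xm)),
            class = "methyl_predictor")
}

#' Support-vector regression predictor
#'
#' Epsilon-insensitive support vector regression with a radial basis
#' kernel at fixed hyperparameters `gamma = 3`, `epsilon = 0.1` and cost
#' `C = 1` (none are tuned). Features and the outcome are standardized
#' internally (the epsilon tube is a width on the unit-variance outcome
#' scale; predictions are mapped back) and the standardization is stored
#' with the model. The fixed bandwidth is
#' interpreted per standardized feature, i.e. the kernel is
#' \eqn{\exp(-\gamma \|x - z\|^2 / p)} for `p` features: a
#' dimension-independent reading is the only one under which a fixed
#' `gamma = 3` is usable on thousands of CpGs (on the raw summed squared
#' distance the kernel matrix of any high-dimensional input collapses to
#' the identity and the fitted predictor is a constant).
#'
#' @inheritParams fit_spca_predictor
#' @param gamma,epsilon,cost SVM hyperparameters; `gamma` is the
#'   bandwidth per standardized feature.
#' @return A `methyl_predictor` (method `"SVM"`).
#' @export
fit_svm_regression <- function(x, ph, gamma = 3, epsilon = 0.1, cost = 1) {
  stopifnot(inherits(ph, "phenotype"))
  xm <- unwrap(x)
  y <- pheno_values(ph)
  if (length(y) < 2L) stop("need at least 2 training samples")
  ctr <- rowMeans(xm)
  scl <- sqrt(row_vars(xm))
  keep <- scl > 0
  xs <- (xm[keep, , drop = FALSE] - ctr[keep]) / scl[keep]
  # the outcome is standardized too (epsilon = 0.1 is a tube width on the
  # unit-variance scale); predictions are mapped back
  ym <- mean(y); ys <- stats::sd(y)
  if (ys == 0) stop("phenotype is constant")
  fit <- e1071::svm(x = t(xs), y = (y - ym) / ys, type = "eps-regression",
                    kernel = "radial", gamma = gamma / nrow(xs),
                    epsilon = epsilon, cost = cost, scale = FALSE)
  structure(list(method = "SVM", fit = fit, features = rownames(xm)[keep],
                 center = ctr[keep], scale = scl[keep],
                 y_center = ym, y_scale = ys),
            class = "methyl_predictor")
}

#' Predict from a fitted methylation predictor
#'
#' @param object A `methyl_predictor`.
#' @param newdata A [methyl_matrix()] or numeric matrix (CpGs x samples)
#'   containing at least the model's training features.
#' @param ... Unused.
#' @return Numeric vector of predictor scores, one per column of
#'   `newdata`.
#' @export
predict.methyl_predictor <- function(object, newdata, ...) {
  xm <- unwrap(newdata)
  miss <- setdiff(object$features, rownames(xm))
  if (length(miss) > 0L) {
    stop(sprintf("newdata lacks %d model features (e.g. %s)",
                 length(miss), miss[1]))
  }
  xm <- xm[object$features, , drop = FALSE]
  out <- switch(object$method,
    SPCA = {
      proj <- crossprod(xm - object$center, object$loadings)
      as.numeric(cbind(1, proj) %*% object$coef)
    },
    ELNET = as.numeric(stats::predict(object$fit, newx = t(xm),
                                      s = object$lambda)),
    SVM = {
      xs <- (xm - object$center) / object$scale
      as.numeric(stats::predict(object$fit, newdata = t(xs))) *
        object$y_scale + object$y_center
    },
    stop("unknown predictor method"))
  stats::setNames(out, colnames(xm))
}

#' @export
print.methyl_predictor <- function(x, ...) {
  extra <- switch(x$method,
                  SPCA = sprintf("%d components, %d features",
                                 x$n_components, length(x$features)),
                  ELNET = sprintf("alpha = %g, lambda = %.4g", x$alpha,
                                  x$lambda),
                  SVM = sprintf("%d features", length(x$features)))
  cat(sprintf("methyl_predictor: %s (%s)\n", x$method, extra))
  invisible(x)
}

#' Compare classification algorithms over repeated partitions
#'
#' Fits SPCA with 1, 2 and 3 components, LASSO (`alpha = 1`), the elastic
#' net (`alpha = 0.05`) and fixed-hyperparameter SVM regression on the
#' training half of every partition, scores the test half, and records
#' the C-index of each method and partition.
#'
#' @param x [methyl_matrix()] covering all samples.
#' @param ph Continuous [phenotype()] (e.g. age).
#' @param partitions A [make_partitions()] result.
#' @param seed Base seed for the internal cross-validations.
#' @param methods Subset of
#'   `c("SPCA-1","SPCA-2","SPCA-3","LASSO","ELNET","SVM")`.
#' @return A data frame (class `classifier_comparison`) with columns
#'   `partition`, `method`, `c_index`.
#' @seealso [summarize_comparison()]
#' @export
run_classifier_comparison <- function(x, ph, partitions, seed = 1,
                                      methods = c("SPCA-1", "SPCA-2",
                                                  "SPCA-3", "LASSO",
                                                  "ELNET", "SVM")) {
  stopifnot(inherits(partitions, "partition_set"))
  if (phenotype_type(ph) != "continuous") {
    stop("classifier comparison uses a continuous phenotype")
  }
  xm <- unwrap(x)
  rows <- list()
  n_spca <- sum(grepl("^SPCA-", methods))
  spca_k <- as.integer(sub("^SPCA-", "", grep("^SPCA-", methods,
                                              value = TRUE)))
  for (j in seq_len(partitions$n_partitions)) {
    pr <- partitions$partitions[[j]]
    xtr <- xm[, pr$train, drop = FALSE]
    xte <- xm[, pr$test, drop = FALSE]
    ptr <- pheno_subset(ph, pr$train)
    yte <- pheno_values(pheno_subset(ph, pr$test))
    preds <- list()
    if (n_spca > 0) {
      fits <- .spca_cv(xtr, ptr, max(spca_k), min_features = 10,
                       max_features = 5000, n_thresholds = 7,
                       nfolds = 10, seed = seed + j)
      for (k in spca_k) {
        preds[[paste0("SPCA-", k)]] <- predict(fits[[k]], xte)
      }
    }
    if ("LASSO" %in% methods) {
      preds$LASSO <- predict(fit_elastic_net(xtr, ptr, alpha = 1,
                                             seed = seed + j), xte)
    }
    if ("ELNET" %in% methods) {
      preds$ELNET <- predict(fit_elastic_net(xtr, ptr, alpha = 0.05,
                                             seed = seed + j), xte)
    }
    if ("SVM" %in% methods) {
      preds$SVM <- predict(fit_svm_regression(xtr, ptr), xte)
    }
    for (m in names(preds)) {
      ci <- if (stats::var(preds[[m]]) == 0) {
        0.5  # constant predictor: every comparable pair is a tie
      } else {
        evaluate_cindex(preds[[m]], yte)$c_index
      }
      rows[[length(rows) + 1L]] <- data.frame(partition = j, method = m,
                                              c_index = ci,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("classifier_comparison", "data.frame")
  out
}

#' Summarize a classifier comparison
#'
#' @param comparison A [run_classifier_comparison()] result.
#' @return List with `medians` (per-method median C-index) and `pairwise`
#'   (data frame of two-sided Wilcoxon rank-sum p-values between methods).
#' @export
summarize_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "classifier_comparison"))
  meds <- tapply(comparison$c_index, comparison$method, stats::median)
  ms <- names(meds)
  pairs <- utils::combn(ms, 2)
  pw <- data.frame(method_a = pairs[1, ], method_b = pairs[2, ],
                   p_value = apply(pairs, 2, function(pr) {
                     compare_ppv(comparison$c_index[comparison$method == pr[1]],
                                 comparison$c_index[comparison$method == pr[2]])$p_value
                   }), stringsAsFactors = FALSE)
  list(medians = meds, pairwise = pw)
}
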