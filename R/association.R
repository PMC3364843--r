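#' Per-CpG association tables
#'
#' All supervised statistics return an `assoc_table`: a data frame with one
#' row per CpG and columns `cpg`, `stat`, `p`, `q`, `direction`
#' (`sign(stat)`), `mean_diff` (class-mean difference for binary
#' phenotypes, regression slope for continuous ones), `var` (pooled or
#' residual variance) and `df`. CpGs with zero variance get `NA`
#' statistics and are excluded from ranking and q-value estimation.
#'
#' @name assoc_table
NULL

.make_assoc_table <- function(cpg, stat, p, mean_diff, var, df) {
  p <- pmax(p, .Machine$double.xmin)  # underflowed p stays in (0, 1]
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- qvalues(p[ok])
  out <- data.frame(cpg = cpg, stat = stat, p = p, q = q,
                    direction = sign(stat), mean_diff = mean_diff,
                    var = var, df = df,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_table", "data.frame")
  out
}

.binary_group_stats <- function(xm, y) {
  g0 <- xm[, y == 0, drop = FALSE]
  g1 <- xm[, y == 1, drop = FALSE]
  n0 <- ncol(g0); n1 <- ncol(g1)
  if (n0 < 2L || n1 < 2L) stop("need at least 2 samples per class")
  list(n0 = n0, n1 = n1,
       m0 = rowMeans(g0), m1 = rowMeans(g1),
       v0 = row_vars(g0), v1 = row_vars(g1))
}

#' Two-sample t-statistics for every CpG
#'
#' Pooled-variance two-sample t test of each CpG against a binary
#' phenotype, with two-sided p-values on `n0 + n1 - 2` degrees of freedom.
#' The pooled form is the default because the empirical-Bayes moderated t
#' ([moderated_t()]) is built on pooled variances and reduces to this
#' statistic when no shrinkage is applied; set `welch = TRUE` for the
#' unequal-variance variant.
#'
#' @param x A [methyl_matrix()] or numeric matrix (CpGs x samples).
#' @param ph Binary [phenotype()] for the columns of `x`.
#' @param welch Use the Welch statistic instead of the pooled one.
#' @return An [assoc_table].
#' @export
t_test_by_feature <- function(x, ph, welch = FALSE) {
  stopifnot(inherits(ph, "phenotype"))
  if (phenotype_type(ph) != "binary") stop("phenotype must be binary")
  xm <- unwrap(x)
  y <- pheno_values(ph)
  if (ncol(xm) != length(y)) stop("matrix and phenotype sizes differ")
  gs <- .binary_group_stats(xm, y)
  md <- gs$m1 - gs$m0
  if (welch) {
    se2 <- gs$v0 / gs$n0 + gs$v1 / gs$n1
    df <- se2^2 / ((gs$v0 / gs$n0)^2 / (gs$n0 - 1) +
                     (gs$v1 / gs$n1)^2 / (gs$n1 - 1))
    pooled <- se2 / (1 / gs$n0 + 1 / gs$n1)  # reported variance
    se <- sqrt(se2)
  } else {
    df <- rep(gs$n0 + gs$n1 - 2, nrow(xm))
    pooled <- ((gs$n0 - 1) * gs$v0 + (gs$n1 - 1) * gs$v1) / df
    se <- sqrt(pooled * (1 / gs$n0 + 1 / gs$n1))
  }
  stat <- md / se
  bad <- !is.finite(stat)
  stat[bad] <- NA_real_
  p <- 2 * stats::pt(-abs(stat), df)
  .make_assoc_table(rownames(xm), stat, p, md, pooled, df)
}

#' Simple linear-regression statistics for every CpG
#'
#' Regresses each CpG's methylation on a continuous phenotype and reports
#' the slope t-statistic on `n - 2` degrees of freedom; `direction` is the
#' sign of the slope and `mean_diff` carries the slope itself.
#'
#' @param x A [methyl_matrix()] or numeric matrix (CpGs x samples).
#' @param ph Continuous [phenotype()] for the columns of `x`.
#' @return An [assoc_table].
#' @export
linear_assoc <- function(x, ph) {
  stopifnot(inherits(ph, "phenotype"))
  if (phenotype_type(ph) != "continuous") stop("phenotype must be continuous")
  xm <- unwrap(x)
  y <- pheno_values(ph)
  n <- length(y)
  if (ncol(xm) != n) stop("matrix and phenotype sizes differ")
  if (n < 3L) stop("need at least 3 samples")
  yc <- y - mean(y)
  sxx <- sum(yc * yc)
  if (sxx == 0) stop("phenotype is constant")
  slope <- as.numeric(xm %*% yc) / sxx
  rm0 <- rowMeans(xm)
  syy <- rowSums(xm * xm) - n * rm0 * rm0
  sse <- pmax(syy - slope^2 * sxx, 0)
  df <- n - 2L
  sigma2 <- sse / df
  se <- sqrt(sigma2 / sxx)
  stat <- slope / se
  stat[!is.finite(stat)] <- NA_real_
  # a CpG fitting exactly (sse == 0) has an effectively infinite statistic;
  # keep it rankable with a p-value at the numerical floor
  exact <- sigma2 == 0 & slope != 0
  if (any(exact)) stat[exact] <- sign(slope[exact]) * 1e12
  p <- 2 * stats::pt(-abs(stat), df)
  .make_assoc_table(rownames(xm), stat, p, slope, sigma2,
                    rep(df, nrow(xm)))
}

#' Empirical-Bayes prior for per-CpG variances
#'
#' Fits a scaled inverse-chi-square prior \eqn{s_0^2, d_0} to a vector of
#' per-feature sample variances by matching the first two moments of
#' \eqn{\log s^2} to their theoretical digamma/trigamma expressions. The
#' trigamma inverse is solved by a monotone Newton iteration. When the
#' observed spread of log-variances does not exceed what sampling alone
#' implies, the prior degrees of freedom are infinite and `s0_squared` is
#' the geometric-mean-based point estimate.
#'
#' @param s2 Per-feature sample variances (all positive; zero variances
#'   should be removed by the caller).
#' @param df Residual degrees of freedom of each variance (scalar).
#' @return A list of class `prior_estimate` with `d0` (possibly `Inf`) and
#'   `s0_squared`.
#' @export
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 2L) stop("need at least 2 variances")
  if (any(s2 <= 0)) stop("variances must be positive")
  stopifnot(length(df) == 1L, df >= 1)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  if (stats::var(log(s2)) < 1e-15) {
    # no spread at all: the prior is a point mass at the common variance
    return(structure(list(d0 = Inf, s0_squared = exp(mean(log(s2)))),
                     class = "prior_estimate"))
  }
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  structure(list(d0 = d0, s0_squared = s0), class = "prior_estimate")
}

#' Inverse of the trigamma function
#'
#' Solves \eqn{\psi'(x) = y} for `x > 0` by Newton iteration on the
#' reciprocal scale, where the function is nearly linear; converges to
#' around 1e-8 relative accuracy in a handful of steps.
#'
#' @param y Positive value(s) of the trigamma function.
#' @return `x` with `trigamma(x) = y` (vectorized).
#' @export
trigamma_inverse <- function(y) {
  stopifnot(all(is.finite(y)), all(y > 0))
  # asymptotes: trigamma(x) ~ 1/x for large x, ~ 1/x^2 for small x
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Moderated (regularized) t-statistics
#'
#' Shrinks each CpG's pooled variance toward the empirical-Bayes prior,
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' and forms \eqn{\tilde t_g = (\bar x_{g1}-\bar x_{g0}) /
#' (\tilde s_g \sqrt{1/n_0 + 1/n_1})} with two-sided p-values on
#' \eqn{d_0 + d_g} degrees of freedom (capped at 1e6 when the prior
#' degrees of freedom are infinite). With `d0 = 0` the statistic is
#' exactly the ordinary pooled t; with `d0 = Inf` every feature uses
#' `s0_squared`. This is the ranking statistic of choice when per-class
#' sample sizes are too small for ordinary t-statistics.
#'
#' @inheritParams t_test_by_feature
#' @param prior Optional [fit_variance_prior()] result; fitted on the
#'   matrix's own pooled variances (zero variances excluded) when `NULL`.
#' @return An [assoc_table] with an attached `prior` attribute.
#' @export
moderated_t <- function(x, ph, prior = NULL) {
  stopifnot(inherits(ph, "phenotype"))
  if (phenotype_type(ph) != "binary") stop("phenotype must be binary")
  xm <- unwrap(x)
  y <- pheno_values(ph)
  if (ncol(xm) != length(y)) stop("matrix and phenotype sizes differ")
  gs <- .binary_group_stats(xm, y)
  dg <- gs$n0 + gs$n1 - 2
  s2 <- ((gs$n0 - 1) * gs$v0 + (gs$n1 - 1) * gs$v1) / dg
  if (is.null(prior)) prior <- fit_variance_prior(s2[s2 > 0], dg)
  stopifnot(inherits(prior, "prior_estimate"))
  d0 <- prior$d0
  s2t <- if (is.infinite(d0)) {
    rep(prior$s0_squared, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$s0_squared + dg * s2) / (d0 + dg)
  }
  md <- gs$m1 - gs$m0
  se <- sqrt(s2t * (1 / gs$n0 + 1 / gs$n1))
  stat <- md / se
  stat[!is.finite(stat)] <- NA_real_
  df_tot <- min(d0 + dg, 1e6)
  p <- 2 * stats::pt(-abs(stat), df_tot)
  out <- .make_assoc_table(rownames(xm), stat, p, md, s2t,
                           rep(df_tot, nrow(xm)))
  attr(out, "prior") <- prior
  out
}

#' Storey q-values
#'
#' False-discovery-rate adjusted significance values
#' \deqn{q(p_{(i)}) = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j,}
#' capped at 1. The null proportion \eqn{\hat\pi_0} is estimated with the
#' fixed-lambda estimator \eqn{\#\{p > \lambda\} / (m(1-\lambda))} at
#' `lambda = 0.5` (deterministic and robust at small `m`), bounded into
#' `(0, 1]`. Forcing `pi0 = 1` reproduces the Benjamini-Hochberg adjusted
#' p-values exactly.
#'
#' @param p P-values in `(0, 1]`.
#' @param pi0 Optional fixed null proportion; estimated when `NULL`.
#' @param lambda Tuning constant of the pi0 estimator.
#' @return Q-values in the original order of `p`.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = 0.5) {
  m <- length(p)
  if (m < 1L) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (is.null(pi0)) {
    pi0 <- sum(p > lambda) / (m * (1 - lambda))
    pi0 <- min(pi0, 1)
    pi0 <- max(pi0, 1 / m)
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))[ro]
  attr(q, "pi0") <- pi0
  q
}
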