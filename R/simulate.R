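#' Configuration for the synthetic methylation-data generator
#'
#' Defines one simulated Infinium-style study. CpG baseline means are drawn
#' from a tri-modal mixture on the logit scale (unmethylated /
#' hemi-methylated / methylated), per-sample values combine logit-normal
#' biological variation with beta-distributed technical sampling noise, and
#' a chosen number of truth CpGs carry a phenotype-driven logit shift whose
#' magnitude is calibrated so the median realized beta-scale effect size
#' over the truth set matches `target_effect_size`.
#'
#' @param n_features Number of CpGs.
#' @param n_per_group Samples per phenotype class (binary) or total number
#'   of samples (continuous).
#' @param phenotype_type `"binary"` (e.g. cancer/normal) or `"continuous"`
#'   (e.g. age).
#' @param n_true Number of truly associated CpGs ("signal strength").
#' @param target_effect_size Dimensionless effect size. Binary: Cohen's-d
#'   style mean difference over pooled SD on the beta scale. Continuous:
#'   standardized slope (beta-scale change per phenotype SD over residual
#'   SD).
#' @param effect_size_spread Log-normal spread of per-CpG effect sizes
#'   around `target_effect_size` (SD on the log scale, normal deviate
#'   truncated at +/- 2). At the default 0 every truth CpG carries the
#'   target effect exactly; positive values emulate the effect-size
#'   heterogeneity of real studies, keeping the median at the target.
#' @param precision Concentration of the beta-distributed technical noise
#'   (must exceed 2; larger is less noisy).
#' @param bio_sd Standard deviation of the logit-scale biological
#'   (between-sample) variation; this layer makes beta values
#'   heteroscedastic while M values stay close to homoscedastic.
#' @param shared_factor_sd Per-sample heterogeneity of the latent
#'   phenotype-linked factor through which all truth CpGs act (default 0:
#'   the phenotype itself is the factor). A positive value makes truth
#'   CpGs mutually correlated beyond their phenotype association and
#'   caps the attainable per-CpG effect size, emulating regimes where
#'   associations are mediated by a variable biological process such as
#'   blood cell-type composition or biological aging.
#' @param baseline_mixture List with `weights`, `means` and `sd` of the
#'   logit-scale baseline mixture. Default: 45% unmethylated (mean -3),
#'   10% hemi-methylated (0), 45% methylated (+3), SD 0.5.
#' @param phenotype_range Range of the continuous phenotype, drawn
#'   uniformly (default ages 25 to 90).
#' @param seed Integer RNG seed; all outputs are deterministic given the
#'   configuration.
#' @param intensity_mode If `TRUE`, [simulate_intensities()] may be used to
#'   emit methylated/unmethylated probe intensities instead of beta values.
#' @param intensity_median Median total intensity (lognormal), default
#'   10,000 so virtually all loci exceed 1,000 combined units.
#' @param intensity_sdlog Lognormal sdlog of the total intensity.
#' @param intensity_noise_sd SD of additive Gaussian probe noise (may
#'   produce negative intensities, as after background subtraction).
#' @return A `sim_config` list.
#' @seealso [simulate_beta_matrix()], [simulate_intensities()]
#' @export
sim_config <- function(n_features = 10000, n_per_group = 50,
                       phenotype_type = c("binary", "continuous"),
                       n_true = 0, target_effect_size = 0,
                       effect_size_spread = 0,
                       precision = 200, bio_sd = 0.35,
                       shared_factor_sd = 0,
                       baseline_mixture = list(weights = c(0.45, 0.10, 0.45),
                                               means = c(-3, 0, 3),
                                               sd = 0.5),
                       phenotype_range = c(25, 90), seed = 1,
                       intensity_mode = FALSE, intensity_median = 10000,
                       intensity_sdlog = 0.5, intensity_noise_sd = 100) {
  phenotype_type <- match.arg(phenotype_type)
  stopifnot(
    n_features >= 1, n_per_group >= 2,
    n_true >= 0, n_true <= n_features,
    target_effect_size >= 0,
    effect_size_spread >= 0,
    precision > 2,
    bio_sd >= 0,
    shared_factor_sd >= 0,
    length(baseline_mixture$weights) == length(baseline_mixture$means),
    baseline_mixture$sd >= 0,
    intensity_median > 0, intensity_sdlog >= 0, intensity_noise_sd >= 0
  )
  if (abs(sum(baseline_mixture$weights) - 1) > 1e-8) {
    stop("baseline mixture weights must sum to 1")
  }
  if (n_true > 0 && target_effect_size > 0 && phenotype_type == "binary" &&
      n_per_group < 2) {
    stop("need at least 2 samples per group")
  }
  structure(list(
    n_features = as.integer(n_features),
    n_per_group = as.integer(n_per_group),
    phenotype_type = phenotype_type,
    n_true = as.integer(n_true),
    target_effect_size = target_effect_size,
    effect_size_spread = effect_size_spread,
    precision = precision,
    bio_sd = bio_sd,
    shared_factor_sd = shared_factor_sd,
    baseline_mixture = baseline_mixture,
    phenotype_range = phenotype_range,
    seed = as.integer(seed),
    intensity_mode = isTRUE(intensity_mode),
    intensity_median = intensity_median,
    intensity_sdlog = intensity_sdlog,
    intensity_noise_sd = intensity_noise_sd
  ), class = "sim_config")
}

# ---- deterministic moments of the noise model --------------------------
# A CpG with logit-scale center `lc` emits
#   value ~ Beta(mean = plogis(lc + bio_sd * Z), concentration = precision)
# with Z standard normal. Mean and variance of the emitted beta value are
# computed by midpoint-quantile quadrature over Z (deterministic, so the
# effect-size calibration does not consume random numbers).
.probit_grid <- function(k = 32) stats::qnorm((seq_len(k) - 0.5) / k)

.beta_moments <- function(lc, bio_sd, precision, z = .probit_grid()) {
  # bio_sd may vary per CpG (recycled along lc)
  mu <- stats::plogis(matrix(lc, length(lc), length(z)) +
                        outer(rep_len(bio_sd, length(lc)), z))
  m <- rowMeans(mu)
  v_bio <- rowMeans(mu * mu) - m * m
  v_tech <- rowMeans(mu * (1 - mu)) / (1 + precision)
  list(mean = m, var = pmax(v_bio, 0) + v_tech)
}

# Expected beta-scale effect size per truth CpG for a given logit shift
# (delta may be a per-CpG vector). Binary: groups sit at baseline -/+
# delta/2; effect = mean difference over pooled SD. Continuous: logit mean
# moves linearly with the standardized phenotype; effect = |slope per
# phenotype SD| / residual SD. Per-sample heterogeneity of the latent
# factor adds delta * factor_sd of logit-scale noise to every truth CpG,
# which both inflates the pooled SD and caps the attainable effect.
.effect_given_shift <- function(baseline, delta, bio_sd, precision, type,
                                factor_sd = 0) {
  sd_eff <- sqrt(bio_sd^2 + (delta * factor_sd)^2)
  if (type == "binary") {
    g1 <- .beta_moments(baseline + delta / 2, sd_eff, precision)
    g0 <- .beta_moments(baseline - delta / 2, sd_eff, precision)
    (g1$mean - g0$mean) / sqrt((g1$var + g0$var) / 2)
  } else {
    # standardized uniform phenotype grid (mean 0, SD 1)
    g <- (seq(0.5 / 16, 1 - 0.5 / 16, length.out = 16) - 0.5) * sqrt(12)
    mm <- matrix(0, length(baseline), length(g))
    vv <- matrix(0, length(baseline), length(g))
    for (l in seq_along(g)) {
      mo <- .beta_moments(baseline + delta * g[l], sd_eff, precision)
      mm[, l] <- mo$mean
      vv[, l] <- mo$var
    }
    slope <- (mm %*% g) / sum(g * g)
    fit <- rowMeans(mm) + slope %*% t(g)
    resid_var <- rowMeans(vv) + rowMeans((mm - fit)^2)
    as.numeric(slope) / sqrt(resid_var)
  }
}

# Per-CpG bisection of the logit shift so that every truth CpG's expected
# beta-scale effect size matches the target. Calibrating each CpG
# individually decouples detectability from baseline variance: a truth CpG
# sitting near the methylated/unmethylated extremes (low beta-scale
# variance) carries the same effect size as a hemi-methylated one.
.calibrate_shift <- function(baseline, target, bio_sd, precision, type,
                             factor_sd = 0, tol = 0.01, max_iter = 50L) {
  nt <- length(baseline)
  if (nt == 0L || all(target == 0)) return(rep(0, nt))
  target <- rep_len(target, nt)
  f <- function(delta) {
    abs(.effect_given_shift(baseline, delta, bio_sd, precision, type,
                            factor_sd))
  }
  hi_val <- 30
  top <- f(rep(hi_val, nt))
  short <- top < target * (1 - tol)
  if (any(short)) {
    comp <- c("unmethylated", "hemi-methylated", "methylated")
    dominant <- comp[findInterval(stats::median(baseline[short]),
                                  c(-1.5, 1.5)) + 1L]
    stop(sprintf(paste0(
      "target effect size %.3g is unattainable for %d truth CpGs ",
      "(predominantly %s): their realized effect saturates at %.3g ",
      "because the group means cannot separate further inside (0,1) ",
      "at this precision/heterogeneity"),
      max(target[short]), sum(short), dominant, max(top[short])))
  }
  lo <- rep(0, nt)
  hi <- rep(hi_val, nt)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    up <- val < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(abs(val - target) / target) <= tol) break
  }
  (lo + hi) / 2
}

# Shared generative core; callers wrap it in with_seed(). `delta` is the
# per-truth-CpG logit shift from the calibration.
.sim_core <- function(config) {
  cfg <- config
  p <- cfg$n_features
  mix <- cfg$baseline_mixture
  comp <- sample.int(length(mix$weights), p, replace = TRUE,
                     prob = mix$weights)
  baseline <- stats::rnorm(p, mix$means[comp], mix$sd)
  feature_ids <- paste0("cg", formatC(seq_len(p), width = 8, flag = "0"))

  if (cfg$phenotype_type == "binary") {
    n <- 2L * cfg$n_per_group
    y <- rep(c(0, 1), each = cfg$n_per_group)
  } else {
    n <- cfg$n_per_group
    y <- stats::runif(n, cfg$phenotype_range[1], cfg$phenotype_range[2])
  }
  sample_ids <- paste0("S", seq_len(n))
  ph <- phenotype(stats::setNames(y, sample_ids), cfg$phenotype_type)

  truth_idx <- if (cfg$n_true > 0) {
    sort(sample.int(p, cfg$n_true))
  } else integer(0)
  signs <- sample(c(-1, 1), length(truth_idx), replace = TRUE)
  targets <- if (cfg$effect_size_spread > 0 && length(truth_idx) > 0) {
    z <- pmin(pmax(stats::rnorm(length(truth_idx)), -2), 2)
    cfg$target_effect_size * exp(cfg$effect_size_spread * z)
  } else {
    rep(cfg$target_effect_size, length(truth_idx))
  }

  delta <- .calibrate_shift(baseline[truth_idx], targets,
                            cfg$bio_sd, cfg$precision, cfg$phenotype_type,
                            cfg$shared_factor_sd)

  # per-sample value of the latent phenotype-linked factor
  xs <- if (cfg$phenotype_type == "binary") {
    y - 0.5
  } else {
    as.numeric(scale(y))
  }
  latent <- xs + stats::rnorm(n, 0, cfg$shared_factor_sd)

  logit_mean <- matrix(baseline, p, n)
  if (length(truth_idx) > 0 && any(delta > 0)) {
    logit_mean[truth_idx, ] <- logit_mean[truth_idx, ] +
      (signs * delta) %*% t(latent)
  }
  logit_mean <- logit_mean + matrix(stats::rnorm(p * n, 0, cfg$bio_sd), p, n)
  mu <- pmin(pmax(stats::plogis(logit_mean), 1e-6), 1 - 1e-6)
  vals <- stats::rbeta(p * n, mu * cfg$precision, (1 - mu) * cfg$precision)
  vals <- matrix(pmin(pmax(vals, 1e-6), 1 - 1e-6), p, n,
                 dimnames = list(feature_ids, sample_ids))

  expected_effect <- if (length(truth_idx) > 0 && any(delta > 0)) {
    abs(.effect_given_shift(baseline[truth_idx], delta, cfg$bio_sd,
                            cfg$precision, cfg$phenotype_type,
                            cfg$shared_factor_sd))
  } else {
    rep(0, length(truth_idx))
  }
  truth <- structure(list(
    true_feature_ids = feature_ids[truth_idx],
    per_feature_effect = stats::setNames(signs * expected_effect,
                                         feature_ids[truth_idx]),
    per_feature_direction = stats::setNames(signs, feature_ids[truth_idx]),
    logit_shift = delta
  ), class = "synthetic_truth")

  list(beta = vals, phenotype = ph, truth = truth)
}

#' Simulate a beta-valued methylation matrix with ground truth
#'
#' Emits a CpG x sample matrix of beta values, the sample phenotype, and
#' the set of truly associated CpGs with their signed expected effect
#' sizes. Noise is a convolution of logit-normal biological variation and
#' beta-distributed technical sampling: variance on the beta scale is
#' maximal for hemi-methylated CpGs and strongly suppressed near 0 and 1
#' (severe heteroscedasticity), while the logit (M) scale is close to
#' homoscedastic. For truth CpGs the phenotype-linked factor shifts the
#' logit mean (split across groups in the binary case) by a per-CpG amount
#' calibrated by bisection so that every truth CpG's expected beta-scale
#' effect size matches `target_effect_size` (within 1% at the level of
#' expected moments), decoupling detectability from baseline variance; an
#' unattainable target raises an error naming the baseline class
#' responsible. All output is deterministic given the config.
#'
#' @param config A [sim_config()].
#' @return A list of class `methyl_sim` with elements `matrix`
#'   (beta-valued [methyl_matrix()]), `phenotype` ([phenotype()]), `truth`
#'   (`synthetic_truth`: `true_feature_ids`, signed `per_feature_effect`,
#'   `per_feature_direction`, and the calibrated `logit_shift`) and
#'   `config`.
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_features = 200, n_per_group = 10,
#'                                        n_true = 20, target_effect_size = 2,
#'                                        seed = 7))
#' range(sim$matrix)
#' @export
simulate_beta_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  core <- with_seed(config$seed, .sim_core(config))
  structure(list(matrix = methyl_matrix(core$beta, "beta"),
                 phenotype = core$phenotype,
                 truth = core$truth,
                 config = config), class = "methyl_sim")
}

#' Simulate paired probe intensities
#'
#' Wraps [simulate_beta_matrix()] in an intensity model: total locus
#' intensity is lognormal with configurable median (default 10,000, so
#' almost all loci exceed the 1,000-unit level typical of real arrays), the
#' methylated/unmethylated split follows the underlying methylation
#' fraction, and additive Gaussian probe noise is applied (negative
#' intensities are possible and left in place; quantification clamps them).
#'
#' @param config A [sim_config()] with `intensity_mode = TRUE`.
#' @return A list of class `methyl_sim_intensities` with elements
#'   `intensities` ([intensity_pair()]), `phenotype`, `truth`, `config`.
#' @export
simulate_intensities <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$intensity_mode) {
    stop("config must have intensity_mode = TRUE")
  }
  out <- with_seed(config$seed, {
    core <- .sim_core(config)
    pmat <- core$beta
    np <- length(pmat)
    total <- matrix(stats::rlnorm(np, log(config$intensity_median),
                                  config$intensity_sdlog),
                    nrow(pmat), ncol(pmat))
    noise_m <- matrix(stats::rnorm(np, 0, config$intensity_noise_sd),
                      nrow(pmat), ncol(pmat))
    noise_u <- matrix(stats::rnorm(np, 0, config$intensity_noise_sd),
                      nrow(pmat), ncol(pmat))
    methy <- total * pmat + noise_m
    unmethy <- total * (1 - pmat) + noise_u
    dimnames(methy) <- dimnames(unmethy) <- dimnames(pmat)
    list(pair = intensity_pair(methy, unmethy), core = core)
  })
  structure(list(intensities = out$pair,
                 phenotype = out$core$phenotype,
                 truth = out$core$truth,
                 config = config), class = "methyl_sim_intensities")
}

#' Realized per-CpG effect sizes for a binary phenotype
#'
#' Cohen's-d style effect per CpG: difference in class means divided by the
#' pooled standard deviation
#' \deqn{d_j = (\bar x_{j1} - \bar x_{j0}) / s_{pool,j},\qquad
#'       s^2_{pool,j} = \frac{(n_0-1)s^2_{j0} + (n_1-1)s^2_{j1}}{n_0+n_1-2}.}
#' CpGs with zero pooled SD report 0 when the means also agree and signed
#' `Inf` otherwise.
#'
#' @param x A [methyl_matrix()] or numeric matrix (CpGs x samples).
#' @param ph A binary [phenotype()] covering the columns of `x`.
#' @return Named numeric vector of signed effect sizes.
#' @export
realized_effect_sizes <- function(x, ph) {
  stopifnot(inherits(ph, "phenotype"))
  if (phenotype_type(ph) != "binary") stop("phenotype must be binary")
  xm <- unwrap(x)
  y <- pheno_values(ph)
  if (ncol(xm) != length(y)) stop("matrix and phenotype sizes differ")
  g0 <- xm[, y == 0, drop = FALSE]
  g1 <- xm[, y == 1, drop = FALSE]
  n0 <- ncol(g0); n1 <- ncol(g1)
  if (n0 < 2L || n1 < 2L) stop("need at least 2 samples per class")
  md <- rowMeans(g1) - rowMeans(g0)
  sp2 <- ((n0 - 1) * row_vars(g0) + (n1 - 1) * row_vars(g1)) / (n0 + n1 - 2)
  sp <- sqrt(sp2)
  d <- md / sp
  zero <- sp == 0
  if (any(zero)) d[zero] <- ifelse(md[zero] == 0, 0, sign(md[zero]) * Inf)
  stats::setNames(d, rownames(xm))
}
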