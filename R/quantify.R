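#' Beta-value quantification from probe intensities
#'
#' Computes fractional methylation as the ratio of the methylated probe
#' signal to the combined locus intensity,
#' \deqn{\beta = \max(methy, 0) / (\max(methy, 0) + \max(unmethy, 0) + 100),}
#' the manufacturer's definition. Negative background-subtracted
#' intensities are clamped at zero and the fixed offset of 100 fluorescence
#' units keeps the denominator positive, so the result always lies in
#' `[0, 1)`.
#'
#' @param pair An [intensity_pair()].
#' @return A [methyl_matrix()] of beta values.
#' @export
compute_beta <- function(pair) {
  stopifnot(inherits(pair, "intensity_pair"))
  m <- pmax(pair$methy, 0)
  u <- pmax(pair$unmethy, 0)
  methyl_matrix(m / (m + u + 100), measure = "beta")
}

#' M-value quantification from probe intensities
#'
#' Computes the log2 ratio of methylated to unmethylated probe intensity,
#' \deqn{M = \log_2((\max(methy, 0) + 1) / (\max(unmethy, 0) + 1)).}
#' The unit offset keeps both numerator and denominator positive. Because
#' typical loci have total intensity above 1,000, the offsets in the beta
#' and M definitions are negligible and the two measures are related
#' approximately by the logistic map of [beta_to_m()].
#'
#' @inheritParams compute_beta
#' @return A [methyl_matrix()] of M values.
#' @export
compute_m <- function(pair) {
  stopifnot(inherits(pair, "intensity_pair"))
  m <- pmax(pair$methy, 0)
  u <- pmax(pair$unmethy, 0)
  methyl_matrix(log2((m + 1) / (u + 1)), measure = "M")
}

#' Convert beta values to M values (logit2 transform)
#'
#' \deqn{M = \log_2(\beta / (1 - \beta))}
#'
#' Values of exactly 0 or 1 have infinite M and are an error by default;
#' supply `clamp` to squeeze the input into `[clamp, 1 - clamp]` first
#' (opt-in, so boundary values in the data are not silently hidden).
#'
#' @param beta A beta-valued [methyl_matrix()] or numeric vector/matrix
#'   with values in `(0, 1)`.
#' @param clamp Optional small positive constant (e.g. `1e-6`).
#' @return M values with the shape of the input; a `methyl_matrix` input
#'   yields a `methyl_matrix` with `measure = "M"`.
#' @export
beta_to_m <- function(beta, clamp = NULL) {
  was_mm <- inherits(beta, "methyl_matrix")
  if (was_mm && measure(beta) != "beta") stop("input is not on the beta scale")
  b <- if (was_mm) unwrap(beta) else beta
  if (!is.null(clamp)) {
    stopifnot(is.numeric(clamp), clamp > 0, clamp < 0.5)
    b <- pmin(pmax(b, clamp), 1 - clamp)
  }
  if (any(b <= 0 | b >= 1)) {
    stop("beta values at 0 or 1 map to infinite M; supply `clamp` to proceed")
  }
  m <- log2(b) - log2(1 - b)
  if (was_mm) methyl_matrix(m, "M") else m
}

#' Convert M values to beta values (inverse logit2 transform)
#'
#' \deqn{\beta = 2^M / (2^M + 1)}
#'
#' Exact inverse of [beta_to_m()]; computed via `plogis` for numerical
#' stability at large `|M|`.
#'
#' @param m An M-valued [methyl_matrix()] or numeric vector/matrix of
#'   finite M values.
#' @return Beta values with the shape of the input.
#' @export
m_to_beta <- function(m) {
  was_mm <- inherits(m, "methyl_matrix")
  if (was_mm && measure(m) != "M") stop("input is not on the M scale")
  v <- if (was_mm) unwrap(m) else m
  if (any(!is.finite(v))) stop("M values must be finite")
  b <- stats::plogis(v * log(2))
  # guard against rounding to exactly 0/1 at extreme M
  b <- pmin(pmax(b, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
  if (was_mm) methyl_matrix(b, "beta") else b
}
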