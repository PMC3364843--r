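#' Truncated SVD decomposition of a methylation matrix
#'
#' Thin singular value decomposition of the feature-centered matrix,
#' components ordered by singular value. The `basis` columns (CpG
#' loadings) are orthonormal; `scores` rows are the per-sample component
#' scores (singular value times right singular vector).
#'
#' @param x A [methyl_matrix()] or numeric matrix (CpGs x samples).
#' @param k Number of components (at most `min(dim(x))`).
#' @return A `decomposition` list: `method = "SVD"`, `basis` (CpGs x k),
#'   `scores` (k x samples), `d` (singular values), `center`, `k`.
#' @export
svd_decompose <- function(x, k) {
  xm <- unwrap(x)
  stopifnot(k >= 1, k <= min(dim(xm)))
  ctr <- rowMeans(xm)
  sv <- svd(xm - ctr, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  zero <- d <= max(sv$d) * 1e-12
  scores <- t(sv$v) * d
  dimnames(scores) <- list(paste0("C", seq_len(k)), colnames(xm))
  basis <- sv$u
  dimnames(basis) <- list(rownames(xm), paste0("C", seq_len(k)))
  structure(list(method = "SVD", basis = basis, scores = scores, d = d,
                 center = ctr, k = k, zero_components = which(zero)),
            class = "decomposition")
}

#' Permutation-based estimate of the number of components
#'
#' Compares the observed singular-value spectrum of the feature-centered
#' matrix with spectra obtained after randomly permuting the entries of
#' every CpG row independently. Row-wise permutation destroys all
#' between-sample structure while preserving each CpG's marginal
#' distribution, so the null spectrum respects the severe
#' heteroscedasticity of beta values (a joint permutation of all entries
#' would homogenize row variances and misstate the null). The estimate is
#' the length of the leading run of observed singular values exceeding
#' the chosen quantile of the matched-rank permuted singular values.
#'
#' @param x A [methyl_matrix()] or numeric matrix.
#' @param n_permutations Number of entry permutations (at least 10).
#' @param quantile Exceedance quantile of the permuted spectrum
#'   (default 0.95); at 0 the estimate counts eigenvalues above the
#'   permutation minimum.
#' @param seed RNG seed for the permutations.
#' @return Integer component count (possibly 0).
#' @export
estimate_n_components <- function(x, n_permutations = 50, quantile = 0.95,
                                  seed = 1) {
  stopifnot(n_permutations >= 10, quantile >= 0, quantile <= 1)
  xm <- unwrap(x)
  r <- min(dim(xm))
  xc <- xm - rowMeans(xm)
  obs <- svd(xc, nu = 0, nv = 0)$d
  n <- ncol(xc)
  rowidx <- row(xc)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      # permute within every row, vectorized via random sort keys
      ord <- order(rowidx, stats::runif(length(xc)))
      xp <- matrix(xc[ord], nrow(xc), n, byrow = TRUE)
      svd(xp, nu = 0, nv = 0)$d
    }, numeric(r))
  })
  thr <- apply(perm, 1, stats::quantile, probs = quantile, names = FALSE)
  exceed <- obs > thr
  if (!exceed[1]) return(0L)
  which.min(c(exceed, FALSE)) - 1L   # length of the leading TRUE run
}

#' Non-negative double SVD (NNDSVD) initialization
#'
#' Deterministic initialization for NMF built from the truncated SVD: the
#' leading singular triplet is used directly (entrywise absolute values),
#' and every further component keeps whichever nonnegative section
#' (positive or negative parts) of its singular-vector pair has the
#' larger norm product, scaled by the singular value. Zeros are left as
#' zeros (no random or mean fill), so the initialization, and any NMF
#' started from it, is identical across runs.
#'
#' @param x Nonnegative numeric matrix (or beta-valued
#'   [methyl_matrix()]).
#' @param k Number of components.
#' @return List with nonnegative `basis` (rows x k) and `scores`
#'   (k x columns) whose product approximates `x`.
#' @export
nndsvd_init <- function(x, k) {
  xm <- unwrap(x)
  if (any(xm < 0)) stop("NNDSVD requires a nonnegative matrix")
  stopifnot(k >= 1, k <= min(dim(xm)))
  sv <- svd(xm, nu = k, nv = k)
  w <- matrix(0, nrow(xm), k)
  h <- matrix(0, k, ncol(xm))
  w[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  h[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        sigma <- nup * nvp
        if (sigma > 0) {
          w[, j] <- sqrt(sv$d[j] * sigma) * up / nup
          h[j, ] <- sqrt(sv$d[j] * sigma) * vp / nvp
        }
      } else {
        sigma <- nun * nvn
        if (sigma > 0) {
          w[, j] <- sqrt(sv$d[j] * sigma) * un / nun
          h[j, ] <- sqrt(sv$d[j] * sigma) * vn / nvn
        }
      }
    }
  }
  dimnames(w) <- list(rownames(xm), paste0("C", seq_len(k)))
  dimnames(h) <- list(paste0("C", seq_len(k)), colnames(xm))
  list(basis = w, scores = h)
}

#' NMF by multiplicative Kullback-Leibler updates (Brunet variant)
#'
#' Factorizes a nonnegative matrix `V ~ W H` by the classical
#' multiplicative updates that monotonically decrease the generalized
#' Kullback-Leibler divergence
#' \deqn{D(V\|WH) = \sum_{ij} V_{ij}\log\frac{V_{ij}}{(WH)_{ij}}
#'       - V_{ij} + (WH)_{ij}.}
#' Iteration stops when the relative objective change falls below `tol`
#' or after `max_iter` updates; the objective trace is recorded. Started
#' from [nndsvd_init()], the whole procedure is deterministic. Exact zeros
#' in the initialization are floored at `1e-3 * mean(x)` before iterating:
#' multiplicative updates cannot move mass into an entry that starts at
#' zero (zero locking), which stalls the factorization far from planted
#' optima; the deterministic floor removes the locking while keeping the
#' NNDSVD structure. `WH` is additionally floored at machine epsilon
#' inside the update ratios and the objective.
#'
#' @param x Nonnegative matrix (beta-valued [methyl_matrix()] accepted;
#'   M-valued input is rejected since NMF requires positivity).
#' @param k Number of components.
#' @param init Optional list with `basis`/`scores` (defaults to
#'   [nndsvd_init()]).
#' @param max_iter Maximum number of update sweeps (default 2000).
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @return A `decomposition` list: `method = "NMF"`, nonnegative `basis`
#'   and `scores`, `objective` trace, `k`, `iterations`.
#' @export
nmf_brunet <- function(x, k, init = NULL, max_iter = 2000, tol = 1e-6) {
  if (inherits(x, "methyl_matrix") && measure(x) != "beta") {
    stop("NMF requires nonnegative input; M-valued matrices are not allowed")
  }
  v <- unwrap(x)
  if (any(v < 0)) stop("NMF requires a nonnegative matrix")
  stopifnot(k >= 1, k <= min(dim(v)))
  if (is.null(init)) init <- nndsvd_init(v, k)
  floor_val <- 1e-3 * mean(v)
  w <- pmax(init$basis, floor_val)
  h <- pmax(init$scores, floor_val)
  stopifnot(ncol(w) == k, nrow(h) == k)
  eps <- .Machine$double.eps
  kl <- function(wh) {
    wh <- pmax(wh, eps)
    sum(ifelse(v > 0, v * log(v / wh), 0) - v + wh)
  }
  wh <- w %*% h
  objective <- kl(wh)
  for (it in seq_len(max_iter)) {
    # H update
    h <- h * (crossprod(w, v / pmax(wh, eps))) / pmax(colSums(w), eps)
    wh <- w %*% h
    # W update
    w <- w * ((v / pmax(wh, eps)) %*% t(h)) / rep(pmax(rowSums(h), eps),
                                                  each = nrow(w))
    wh <- w %*% h
    objective <- c(objective, kl(wh))
    delta <- objective[it] - objective[it + 1]
    if (abs(delta) <= tol * max(abs(objective[it]), eps)) break
  }
  dimnames(w) <- list(rownames(v), paste0("C", seq_len(k)))
  dimnames(h) <- list(paste0("C", seq_len(k)), colnames(v))
  structure(list(method = "NMF", basis = w, scores = h,
                 objective = objective, k = k,
                 iterations = length(objective) - 1L),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("decomposition: %s with k = %d (%d features x %d samples)\n",
              x$method, x$k, nrow(x$basis), ncol(x$scores)))
  invisible(x)
}

#' Component-phenotype R-squared
#'
#' Coefficient of determination of a simple linear regression between
#' each component's sample scores and the phenotype (binary phenotypes
#' coded 0/1); for simple regression this is the squared Pearson
#' correlation, so it is symmetric in the two variables and invariant to
#' affine transforms of the scores. The summary is the mean of the two
#' largest R-squared values (or the single value when `k = 1`).
#'
#' @param decomp A `decomposition` from [svd_decompose()] or
#'   [nmf_brunet()].
#' @param ph A [phenotype()] aligned with the decomposition's samples.
#' @return List of class `component_association` with `r2` (per
#'   component) and `best2_avg`.
#' @export
component_phenotype_r2 <- function(decomp, ph) {
  stopifnot(inherits(decomp, "decomposition"), inherits(ph, "phenotype"))
  if (decomp$k < 1L) stop("decomposition has no components")
  y <- pheno_values(ph)
  if (ncol(decomp$scores) != length(y)) {
    stop("decomposition and phenotype sample counts differ")
  }
  r2 <- apply(decomp$scores, 1, function(s) {
    if (stats::var(s) == 0 || stats::var(y) == 0) return(0)
    stats::cor(s, y)^2
  })
  best2 <- mean(sort(r2, decreasing = TRUE)[seq_len(min(2L, length(r2)))])
  structure(list(r2 = r2, best2_avg = best2),
            class = "component_association")
}

#' Compare SVD and NMF modelling of a phenotype
#'
#' Estimates the number of significant components from the permutation
#' spectrum ([estimate_n_components()]; estimates below 2 are raised to 2
#' with a warning, since the summary statistic averages the two best
#' components), decomposes the beta-valued matrix with both SVD and
#' NNDSVD-initialized Brunet NMF at that shared rank, and reports each
#' method's per-component R-squared against the phenotype together with
#' the average of the two best components.
#'
#' @param x Beta-valued [methyl_matrix()].
#' @param ph A [phenotype()].
#' @param n_permutations Permutations for the rank estimate.
#' @param seed RNG seed for the rank estimate.
#' @return List with `k`, `svd` and `nmf` ([component_phenotype_r2()]
#'   results) and the fitted decompositions.
#' @export
compare_svd_nmf <- function(x, ph, n_permutations = 50, seed = 1) {
  stopifnot(inherits(x, "methyl_matrix"))
  if (measure(x) != "beta") stop("comparison runs on beta-valued matrices")
  k <- estimate_n_components(x, n_permutations = n_permutations,
                             seed = seed)
  if (k < 2L) {
    warning(sprintf(paste0("permutation spectrum suggests %d component(s); ",
                           "using k = 2, the minimum for the best-two ",
                           "summary"), k))
    k <- 2L
  }
  sv <- svd_decompose(x, k)
  nm <- nmf_brunet(x, k)
  list(k = k,
       svd = component_phenotype_r2(sv, ph),
       nmf = component_phenotype_r2(nm, ph),
       svd_decomposition = sv, nmf_decomposition = nm)
}
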