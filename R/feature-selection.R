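#' Ranked feature lists
#'
#' The three feature-selection procedures return a `ranked_features` data
#' frame with columns `rank`, `cpg`, `score` (the ranking score: p-value
#' for WF/VF, absolute component loading for SPCA) and `direction` (the
#' sign the phenotype association is expected to have, carried from the
#' training statistics), plus a `method` attribute. Ordering is fully
#' deterministic: primary key ascending p (or descending |loading|), ties
#' broken by larger absolute statistic, then lexicographic CpG ID.
#'
#' @name ranked_features
NULL

.new_ranked <- function(cpg, score, direction, method) {
  out <- data.frame(rank = seq_along(cpg), cpg = cpg, score = score,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "method") <- method
  class(out) <- c("ranked_features", "data.frame")
  out
}

# deterministic significance ordering of an assoc_table (NA stats dropped)
.assoc_order <- function(assoc) {
  keep <- which(!is.na(assoc$stat))
  keep[order(assoc$p[keep], -abs(assoc$stat[keep]), assoc$cpg[keep])]
}

# dispatcher shared by the selection and PPV machinery
.assoc_fun <- function(statistic) {
  switch(statistic,
         t = function(x, ph) t_test_by_feature(x, ph),
         moderated_t = function(x, ph) moderated_t(x, ph),
         linear = function(x, ph) linear_assoc(x, ph),
         stop("unknown statistic: ", statistic))
}

#' Feature selection without filtering (WF)
#'
#' Ranks every CpG of the training association table by significance and
#' returns the top `k` (default 1,500) with their association directions.
#'
#' @param assoc An [assoc_table] computed on the training samples.
#' @param k Number of CpGs to return.
#' @return A [ranked_features] list, method `"WF"`.
#' @export
select_wf <- function(assoc, k = 1500) {
  stopifnot(inherits(assoc, "assoc_table"), k >= 0)
  ord <- .assoc_order(assoc)
  if (k > length(ord)) {
    warning(sprintf("only %d rankable features; truncating k = %d",
                    length(ord), k))
    k <- length(ord)
  }
  ord <- ord[seq_len(k)]
  .new_ranked(assoc$cpg[ord], assoc$p[ord], assoc$direction[ord], "WF")
}

#' Variance filtering (VF) feature selection
#'
#' Step I restricts to the `n_var` (default 5,000) most variable CpGs of
#' the training matrix, computed across all training samples without
#' looking at the phenotype. Step II ranks those by the significance of
#' the supervised statistic and keeps `min(k, #\{p < 0.05\})` of them, so
#' the returned list never includes unfiltered-but-insignificant CpGs.
#'
#' @param x Training [methyl_matrix()] (or numeric matrix).
#' @param ph Training [phenotype()].
#' @param k Maximum list length (default 1,500).
#' @param n_var Size of the variance filter (default 5,000); when the
#'   matrix has fewer features all are kept and a message is emitted.
#' @param statistic `"t"`, `"moderated_t"` or `"linear"`.
#' @return A [ranked_features] list, method `"VF"`.
#' @export
select_vf <- function(x, ph, k = 1500, n_var = 5000,
                      statistic = c("t", "moderated_t", "linear")) {
  statistic <- match.arg(statistic)
  xm <- unwrap(x)
  stopifnot(k >= 0)
  v <- row_vars(xm)
  if (nrow(xm) < n_var) {
    message(sprintf("matrix has %d < %d features; variance filter keeps all",
                    nrow(xm), n_var))
    n_var <- nrow(xm)
  }
  keep <- order(-v, rownames(xm))[seq_len(n_var)]
  sub <- xm[keep, , drop = FALSE]
  assoc <- .assoc_fun(statistic)(sub, ph)
  ord <- .assoc_order(assoc)
  n_sig <- sum(assoc$p[ord] < 0.05)
  k_eff <- min(k, n_sig)
  ord <- ord[seq_len(k_eff)]
  .new_ranked(assoc$cpg[ord], assoc$p[ord], assoc$direction[ord], "VF")
}

#' Supervised principal components (SPCA) feature selection
#'
#' Steps: (I-II) rank all CpGs by the supervised statistic and keep the
#' `n_sig` (default 5,000) most significant; (III) run an SVD of that
#' feature-centered submatrix and pick the component whose sample-score
#' vector has maximal absolute Pearson correlation with the phenotype
#' (binary phenotypes coded 0/1; components examined up to
#' `min(n - 1, max_components)`); (IV) rank the candidate CpGs by the
#' absolute value of their loading on the chosen component and return the
#' top `k`. Each CpG's `direction` is
#' `sign(loading x cor(component, phenotype))`, which is invariant to the
#' arbitrary sign of the singular vectors.
#'
#' @inheritParams select_vf
#' @param n_sig Size of the supervised pre-filter (default 5,000).
#' @param max_components Number of leading components examined (default 30).
#' @return A [ranked_features] list, method `"SPCA"`.
#' @export
select_spca <- function(x, ph, k = 1500, n_sig = 5000,
                        max_components = 30,
                        statistic = c("t", "moderated_t", "linear")) {
  statistic <- match.arg(statistic)
  xm <- unwrap(x)
  stopifnot(k >= 0, ncol(xm) >= 2)
  assoc <- .assoc_fun(statistic)(xm, ph)
  ord <- .assoc_order(assoc)
  n_sig <- min(n_sig, length(ord))
  cand <- assoc$cpg[ord[seq_len(n_sig)]]
  sub <- xm[cand, , drop = FALSE]
  sub <- sub - rowMeans(sub)
  sv <- svd(sub)
  pos <- sv$d > max(sv$d) * 1e-12
  if (!any(pos)) stop("degenerate SVD: candidate matrix has rank 0")
  ncomp <- min(sum(pos), ncol(xm) - 1L, max_components)
  y <- pheno_values(ph)
  r <- suppressWarnings(as.numeric(stats::cor(sv$v[, seq_len(ncomp),
                                                   drop = FALSE], y)))
  r[is.na(r)] <- 0
  sel <- which.max(abs(r))
  loading <- sv$u[, sel]
  direction <- sign(loading * r[sel])
  o2 <- order(-abs(loading), cand)
  k_eff <- min(k, length(o2))
  o2 <- o2[seq_len(k_eff)]
  out <- .new_ranked(cand[o2], abs(loading)[o2], direction[o2], "SPCA")
  attr(out, "component") <- sel
  attr(out, "component_cor") <- r[sel]
  out
}
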