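# Shared fixtures, built in code at test time.

# tiny binary phenotype: n0 + n1 samples coded 0/1
binary_pheno <- function(n0, n1, ids = NULL) {
  v <- c(rep(0, n0), rep(1, n1))
  ids <- ids %||% paste0("S", seq_along(v))
  phenotype(stats::setNames(v, ids), "binary")
}

continuous_pheno <- function(values, ids = NULL) {
  ids <- ids %||% paste0("S", seq_along(values))
  phenotype(stats::setNames(values, ids), "continuous")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# matrix with named rows/cols from a numeric vector per feature
feat_matrix <- function(..., ids = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- ids %||% paste0("cg", seq_len(nrow(m)))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

# small default simulation (fast) used by several suites
small_sim <- function(seed = 1, ...) {
  simulate_beta_matrix(sim_config(n_features = 400, n_per_group = 15,
                                  n_true = 40, target_effect_size = 2,
                                  seed = seed, ...))
}

# an assoc_table built directly (for count_true_positives fixtures)
manual_assoc <- function(cpg, p, direction) {
  stat <- direction * stats::qnorm(1 - p / 2)
  out <- data.frame(cpg = cpg, stat = stat, p = p, q = p,
                    direction = direction, mean_diff = stat, var = 1,
                    df = 10, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

manual_ranked <- function(cpg, direction, method = "WF") {
  out <- data.frame(rank = seq_along(cpg), cpg = cpg,
                    score = seq_along(cpg) / length(cpg),
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("ranked_features", "data.frame")
  out
}
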