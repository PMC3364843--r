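# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards so seeded helpers do not
# perturb an enclosing simulation.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Row-wise means and variances without looping.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute row variances")
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1L)
}

# Deterministic fold assignment for internal cross-validation, stratified
# on the outcome by assigning samples to folds in outcome order.
stratified_folds <- function(y, nfolds, seed = NULL) {
  n <- length(y)
  nfolds <- min(nfolds, n)
  with_seed(seed, {
    ord <- order(y, sample.int(n))      # random tie-break within equal y
    foldid <- integer(n)
    foldid[ord] <- rep_len(sample.int(nfolds), n)
    foldid
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
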