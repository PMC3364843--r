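#' Repeated balanced train/test partitions
#'
#' Generates `n_partitions` independent 50/50 splits of the samples.
#' Training and test halves are always of equal size so that p-values
#' computed in the two halves are comparable, and the split is stratified:
#' per class for binary phenotypes, per phenotype-quartile bin for
#' continuous ones, so both halves have similar demographics. When a
#' stratum has an odd count, one randomly chosen surplus sample is left
#' out of that partition entirely.
#'
#' @param ph A [phenotype()].
#' @param n_partitions Number of partitions (default 50).
#' @param seed RNG seed; the partition set is deterministic given it.
#' @return A `partition_set`: list with `partitions` (each a list with
#'   character vectors `train` and `test`), `n_partitions`, `seed`.
#' @export
make_partitions <- function(ph, n_partitions = 50, seed = 1) {
  stopifnot(inherits(ph, "phenotype"), n_partitions >= 1)
  ids <- names(unclass(ph))
  y <- pheno_values(ph)
  if (phenotype_type(ph) == "binary") {
    strata <- split(ids, y)
  } else {
    qs <- stats::quantile(y, c(0.25, 0.5, 0.75))
    strata <- split(ids, findInterval(y, unique(qs)))
  }
  if (any(lengths(strata) < 2L)) {
    stop("every stratum needs at least 2 samples (one per half)")
  }
  parts <- with_seed(seed, {
    lapply(seq_len(n_partitions), function(i) {
      tr <- character(0); te <- character(0)
      for (s in strata) {
        s <- sample(s)                      # random order; surplus dropped
        h <- length(s) %/% 2L
        tr <- c(tr, s[seq_len(h)])
        te <- c(te, s[h + seq_len(h)])
      }
      list(train = tr, test = te)
    })
  })
  structure(list(partitions = parts, n_partitions = n_partitions,
                 seed = seed), class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("partition_set: %d partitions of %d train / %d test samples\n",
              x$n_partitions, length(x$partitions[[1]]$train),
              length(x$partitions[[1]]$test)))
  invisible(x)
}

#' Count test-set true positives among top-ranked training features
#'
#' A training-selected CpG counts as a true positive when its test-set
#' statistic has p < 0.05 *and* the same directional change (sign of the
#' statistic) as in the training set. CpGs absent from the test table, or
#' with unrankable test statistics, count as not positive.
#'
#' @param train_list A [ranked_features] list from the training half.
#' @param test_assoc An [assoc_table] from the matched test half.
#' @param set_size Evaluation-set size (at most `nrow(train_list)`).
#' @return Integer count of true positives.
#' @export
count_true_positives <- function(train_list, test_assoc, set_size) {
  stopifnot(inherits(train_list, "ranked_features"),
            inherits(test_assoc, "assoc_table"),
            set_size >= 0, set_size <= nrow(train_list))
  if (set_size == 0L) return(0L)
  top <- train_list[seq_len(set_size), ]
  idx <- match(top$cpg, test_assoc$cpg)
  p <- test_assoc$p[idx]
  dir <- test_assoc$direction[idx]
  sum(!is.na(p) & p < 0.05 & !is.na(dir) & dir == top$direction,
      na.rm = TRUE)
}

#' Positive-predictive-value matrix over repeated partitions
#'
#' The core evaluation loop: for every partition the supervised statistic
#' is computed on the training half, the chosen feature-selection method
#' produces a ranked list, the same statistic is computed on the test
#' half, and the PPV (true positives / evaluation-set size) is recorded
#' for stepwise evaluation sizes. Evaluation sizes exceeding the ranked
#' list (possible for VF, which truncates at `#\{p < 0.05\}`) are scored
#' over the full list and flagged in the `truncated` attribute.
#'
#' @param x A [methyl_matrix()] covering all partitioned samples.
#' @param ph Matching [phenotype()].
#' @param partitions A [make_partitions()] result.
#' @param method `"WF"`, `"VF"` or `"SPCA"`.
#' @param statistic `"t"`, `"moderated_t"` (binary phenotypes) or
#'   `"linear"` (continuous).
#' @param sizes Evaluation-set sizes (default `seq(50, 1500, by = 50)`).
#' @param k Selected-list length passed to the selection method.
#' @param measure_as Evaluate on the matrix's own scale (`NULL`) or
#'   convert first: `"M"` logit-transforms a beta matrix (clamped at
#'   1e-6), `"beta"` inverse-transforms an M matrix.
#' @return A `ppv_matrix`: numeric matrix (rows = sizes, columns =
#'   partitions) with attributes `sizes`, `method`, `statistic`,
#'   `measure` and `truncated`.
#' @export
ppv_curve <- function(x, ph, partitions, method = c("WF", "VF", "SPCA"),
                      statistic = c("t", "moderated_t", "linear"),
                      sizes = seq(50, 1500, by = 50), k = 1500,
                      measure_as = NULL) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  stopifnot(inherits(partitions, "partition_set"))
  if (statistic == "linear" && phenotype_type(ph) != "continuous") {
    stop("linear statistic requires a continuous phenotype")
  }
  if (statistic != "linear" && phenotype_type(ph) != "binary") {
    stop("t statistics require a binary phenotype")
  }
  x <- .coerce_measure(x, measure_as)
  xm <- unwrap(x)
  meas <- if (inherits(x, "methyl_matrix")) measure(x) else "unknown"
  afun <- .assoc_fun(statistic)
  np <- partitions$n_partitions
  out <- matrix(NA_real_, length(sizes), np,
                dimnames = list(sizes, paste0("run", seq_len(np))))
  trunc <- matrix(FALSE, length(sizes), np)
  for (j in seq_len(np)) {
    pr <- partitions$partitions[[j]]
    res <- tryCatch(
      .ppv_one_partition(xm, ph, pr, method, statistic, afun, sizes, k),
      error = function(e) stop(sprintf("partition %d: %s", j,
                                       conditionMessage(e)), call. = FALSE))
    out[, j] <- res$ppv
    trunc[, j] <- res$truncated
  }
  structure(out, sizes = sizes, method = method, statistic = statistic,
            measure = meas, truncated = trunc,
            class = c("ppv_matrix", "matrix", "array"))
}

.coerce_measure <- function(x, measure_as) {
  if (is.null(measure_as)) return(x)
  stopifnot(inherits(x, "methyl_matrix"))
  if (measure(x) == measure_as) return(x)
  if (measure_as == "M") beta_to_m(x, clamp = 1e-6) else m_to_beta(x)
}

.ppv_one_partition <- function(xm, ph, pr, method, statistic, afun,
                               sizes, k) {
  xtr <- xm[, pr$train, drop = FALSE]
  xte <- xm[, pr$test, drop = FALSE]
  ptr <- pheno_subset(ph, pr$train)
  pte <- pheno_subset(ph, pr$test)
  sel <- switch(method,
                WF = select_wf(afun(xtr, ptr), k = k),
                VF = select_vf(xtr, ptr, k = k, statistic = statistic),
                SPCA = select_spca(xtr, ptr, k = k, statistic = statistic))
  test_assoc <- afun(xte, pte)
  len <- nrow(sel)
  ppv <- numeric(length(sizes))
  truncated <- logical(length(sizes))
  for (i in seq_along(sizes)) {
    eff <- min(sizes[i], len)
    truncated[i] <- sizes[i] > len
    ppv[i] <- if (eff == 0L) NA_real_ else {
      count_true_positives(sel, test_assoc, eff) / eff
    }
  }
  list(ppv = ppv, truncated = truncated)
}

#' Small-sample PPV evaluation
#'
#' Replays the PPV evaluation with tiny training and test sets: each
#' partition draws `n_per_class` samples per class for the training half
#' and a disjoint `n_per_class` per class for the test half from the
#' source matrix. Ordinary t-statistics are unusable at 2-3 samples per
#' class, so the statistic is forced to the moderated t.
#'
#' @inheritParams ppv_curve
#' @param n_per_class Training (and test) samples per class, typically 2
#'   or 3.
#' @param n_partitions Number of random subsample partitions.
#' @param seed RNG seed for the subsampling.
#' @return A `ppv_matrix` (see [ppv_curve()]).
#' @export
small_sample_ppv <- function(x, ph, n_per_class = 2,
                             method = c("WF", "VF", "SPCA"),
                             sizes = seq(50, 1500, by = 50), k = 1500,
                             n_partitions = 50, seed = 1,
                             measure_as = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ph, "phenotype"))
  if (phenotype_type(ph) != "binary") stop("phenotype must be binary")
  ids <- split(names(unclass(ph)), pheno_values(ph))
  if (any(lengths(ids) < 2L * n_per_class)) {
    stop(sprintf("need at least %d samples per class to draw disjoint %d/%d subsets",
                 2L * n_per_class, n_per_class, n_per_class))
  }
  parts <- with_seed(seed, {
    lapply(seq_len(n_partitions), function(i) {
      picks <- lapply(ids, sample, size = 2L * n_per_class)
      list(train = unlist(lapply(picks, `[`, seq_len(n_per_class)),
                          use.names = FALSE),
           test = unlist(lapply(picks, `[`, n_per_class + seq_len(n_per_class)),
                         use.names = FALSE))
    })
  })
  pset <- structure(list(partitions = parts, n_partitions = n_partitions,
                         seed = seed), class = "partition_set")
  ppv_curve(x, ph, pset, method = method, statistic = "moderated_t",
            sizes = sizes, k = k, measure_as = measure_as)
}

#' Compare two PPV samples by Wilcoxon rank-sum test
#'
#' Compares the PPV values of two methods (or measures) at a fixed
#' evaluation-set size across partitions. The partitions are shared by
#' design but treated as independent samples, i.e. an unpaired two-sample
#' rank-sum test by default; set `paired = TRUE` for a signed-rank test.
#'
#' @param a,b Numeric vectors of PPV values (e.g. rows of two
#'   `ppv_matrix` objects), equal length if `paired`.
#' @param alternative Passed to [stats::wilcox.test()].
#' @param paired Use the paired signed-rank variant.
#' @return List with `p_value`, `median_a`, `median_b` and `statistic`.
#' @export
compare_ppv <- function(a, b, alternative = c("two.sided", "less", "greater"),
                        paired = FALSE) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == b[1]) && all(b == b[1])) {
    return(list(p_value = 1, median_a = stats::median(a),
                median_b = stats::median(b), statistic = NA_real_))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            paired = paired))
  list(p_value = wt$p.value, median_a = stats::median(a),
       median_b = stats::median(b), statistic = unname(wt$statistic))
}

#' Choose per-study evaluation-set sizes that equalize PPV
#'
#' Different studies operate at very different false-discovery regimes,
#' so comparing methods across studies is fairer at evaluation sizes that
#' bring the studies' PPVs onto a common level. This grid search scans
#' candidate PPV levels (every observed curve value) and, for each,
#' assigns every study the feasible size whose mean PPV is closest to the
#' level (ties to the smaller size); it returns the assignment minimizing
#' the between-study variance of the resulting PPVs, breaking ties toward
#' smaller sizes.
#'
#' @param curves Named list (one entry per study) of mean-PPV vectors
#'   named by evaluation-set size; all studies must share the size grid.
#' @param min_size,max_size Constraints on admissible sizes.
#' @return Named numeric vector: chosen size per study.
#' @export
choose_evaluation_sizes <- function(curves, min_size = -Inf,
                                    max_size = Inf) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  grids <- lapply(curves, function(cv) as.numeric(names(cv)))
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("all studies must share a common size grid")
  }
  grid <- grids[[1]]
  feas <- which(grid >= min_size & grid <= max_size)
  if (length(feas) == 0L) stop("no feasible evaluation sizes in range")
  cand <- sort(unique(unlist(lapply(curves, `[`, feas))))
  best <- NULL
  for (target in cand) {
    pick <- vapply(curves, function(cv) {
      d <- abs(cv[feas] - target)
      feas[which.min(d)]          # which.min takes the first = smaller size
    }, integer(1))
    vals <- mapply(function(cv, i) cv[i], curves, pick)
    obj <- stats::var(vals)
    score <- c(obj, sum(grid[pick]))
    if (is.null(best) || obj < best$obj - 1e-15 ||
        (abs(obj - best$obj) <= 1e-15 && sum(grid[pick]) < best$sizes_sum)) {
      best <- list(obj = obj, sizes_sum = sum(grid[pick]), pick = pick)
    }
  }
  stats::setNames(grid[best$pick], names(curves))
}

#' Row means of a PPV matrix
#'
#' @param x A `ppv_matrix`.
#' @return Named numeric vector of per-size mean PPVs across partitions.
#' @export
mean_ppv <- function(x) {
  stopifnot(inherits(x, "ppv_matrix"))
  rowMeans(unclass(x)[seq_len(nrow(x)), , drop = FALSE], na.rm = TRUE)
}

#' @export
print.ppv_matrix <- function(x, ...) {
  cat(sprintf("ppv_matrix: %s / %s on %s values; %d sizes x %d partitions\n",
              attr(x, "method"), attr(x, "statistic"), attr(x, "measure"),
              nrow(x), ncol(x)))
  invisible(x)
}
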