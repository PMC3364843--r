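#' Methylation matrix with an attached quantification measure
#'
#' A thin wrapper around a numeric CpG x sample matrix that records which
#' quantification scale the values live on: `"beta"` (fractional
#' methylation in `[0, 1)`) or `"M"` (log2 methylated/unmethylated ratio,
#' any real value).
#'
#' @param values Numeric matrix, CpGs in rows, samples in columns. Row and
#'   column names are used as CpG and sample identifiers; defaults are
#'   generated when missing.
#' @param measure Either `"beta"` or `"M"`.
#' @return A `methyl_matrix`: the input matrix with a `measure` attribute.
#' @examples
#' x <- methyl_matrix(matrix(runif(6), 3, 2), "beta")
#' measure(x)
#' @export
methyl_matrix <- function(values, measure = c("beta", "M")) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("cg", formatC(seq_len(nrow(values)),
                                             width = 8, flag = "0"))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (anyNA(values)) stop("methylation values must not contain NA")
  if (measure == "beta" && (any(values < 0) || any(values >= 1))) {
    stop("beta values must lie in [0, 1)")
  }
  if (measure == "M" && any(!is.finite(values))) {
    stop("M values must be finite")
  }
  structure(values, measure = measure, class = c("methyl_matrix", "matrix", "array"))
}

#' @rdname methyl_matrix
#' @param x A `methyl_matrix`.
#' @export
measure <- function(x) {
  m <- attr(x, "measure")
  if (is.null(m)) stop("object carries no quantification measure")
  m
}

# Strip the class so downstream matrix algebra behaves as for plain
# matrices (subsetting a classed matrix would otherwise drop attributes
# unpredictably).
unwrap <- function(x) {
  if (inherits(x, "methyl_matrix")) {
    attr(x, "measure") <- NULL
    class(x) <- NULL
  }
  as.matrix(x)
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d CpGs x %d samples (%s values)\n",
              nrow(x), ncol(x), attr(x, "measure")))
  invisible(x)
}

#' Paired methylated/unmethylated probe intensities
#'
#' Fluorescence intensities of the methylated and unmethylated probe for
#' each CpG and sample. Values may be negative after background
#' subtraction; quantification clamps them at zero.
#'
#' @param methy,unmethy Numeric matrices of identical dimensions and
#'   dimnames (CpGs x samples).
#' @return An `intensity_pair` (list with elements `methy` and `unmethy`).
#' @export
intensity_pair <- function(methy, unmethy) {
  methy <- as.matrix(methy)
  unmethy <- as.matrix(unmethy)
  if (!identical(dim(methy), dim(unmethy))) {
    stop("methy and unmethy must have identical dimensions")
  }
  if (!identical(dimnames(methy), dimnames(unmethy))) {
    stop("methy and unmethy must have identical dimnames")
  }
  if (is.null(rownames(methy))) {
    rn <- paste0("cg", formatC(seq_len(nrow(methy)), width = 8, flag = "0"))
    rownames(methy) <- rownames(unmethy) <- rn
  }
  if (is.null(colnames(methy))) {
    cn <- paste0("S", seq_len(ncol(methy)))
    colnames(methy) <- colnames(unmethy) <- cn
  }
  structure(list(methy = methy, unmethy = unmethy), class = "intensity_pair")
}

#' @export
print.intensity_pair <- function(x, ...) {
  cat(sprintf("intensity_pair: %d CpGs x %d samples\n",
              nrow(x$methy), ncol(x$methy)))
  invisible(x)
}

#' Sample phenotype vector
#'
#' A named numeric vector of per-sample phenotype values with a type tag.
#' Binary phenotypes (e.g. cancer/normal status) are coded 0/1 and must
#' contain both classes; continuous phenotypes (e.g. age) are real valued.
#'
#' @param values Numeric vector; for `type = "binary"` only values 0 and 1
#'   are allowed.
#' @param type `"binary"` or `"continuous"`.
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   `names(values)`).
#' @return A `phenotype` object (named numeric vector with a `type`
#'   attribute).
#' @export
phenotype <- function(values, type = c("binary", "continuous"),
                      sample_ids = names(values)) {
  type <- match.arg(type)
  values <- as.numeric(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(values))
  if (length(sample_ids) != length(values)) {
    stop("sample_ids must match the number of phenotype values")
  }
  if (anyNA(values)) stop("phenotype values must not be NA")
  if (type == "binary") {
    if (!all(values %in% c(0, 1))) stop("binary phenotype must be coded 0/1")
    if (length(unique(values)) < 2L) {
      stop("binary phenotype must contain both classes")
    }
  }
  structure(stats::setNames(values, sample_ids), type = type,
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("phenotype: %d samples (%s)\n", length(x),
              attr(x, "type")))
  invisible(x)
}

#' @rdname phenotype
#' @param x A `phenotype`.
#' @export
phenotype_type <- function(x) {
  t <- attr(x, "type")
  if (is.null(t)) stop("object carries no phenotype type")
  t
}

# Subset a phenotype keeping its attributes.
pheno_subset <- function(ph, ids) {
  v <- unclass(ph)
  structure(v[ids], type = attr(ph, "type"), class = "phenotype")
}

# Coerce to a plain numeric vector (binary stays 0/1).
pheno_values <- function(ph) as.numeric(unclass(ph))
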