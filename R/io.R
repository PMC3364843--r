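#' Read and write methylation matrices as tab-delimited text
#'
#' The on-disk format is a TSV with the CpG identifier in the first
#' column and one column per sample; the quantification measure is
#' recorded in a `# measure=` comment on the first line so a file round
#' trips with its scale intact.
#'
#' @param x A [methyl_matrix()].
#' @param path File path.
#' @return `write_methyl_matrix` returns `path` invisibly;
#'   `read_methyl_matrix` returns a [methyl_matrix()].
#' @export
write_methyl_matrix <- function(x, path) {
  stopifnot(inherits(x, "methyl_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# measure=%s", measure(x)), con)
  df <- data.frame(cpg = rownames(x), unwrap(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_methyl_matrix
#' @export
read_methyl_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  meas <- sub("^# measure=", "", first)
  if (!meas %in% c("beta", "M")) {
    stop("file lacks a '# measure=' header line")
  }
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  methyl_matrix(m, meas)
}

#' Write an association table as TSV
#'
#' Columns: `cpg`, `stat`, `p`, `q`, `direction`, `mean_diff`, `var`,
#' `df`.
#'
#' @param assoc An [assoc_table].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_assoc_table <- function(assoc, path) {
  stopifnot(inherits(assoc, "assoc_table"))
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a PPV matrix in long format
#'
#' One row per (evaluation size, partition) with the method, measure and
#' statistic tags, suitable for downstream plotting.
#'
#' @param ppv A `ppv_matrix` from [ppv_curve()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ppv_matrix <- function(ppv, path) {
  stopifnot(inherits(ppv, "ppv_matrix"))
  sizes <- attr(ppv, "sizes")
  long <- data.frame(
    size = rep(sizes, times = ncol(ppv)),
    partition = rep(seq_len(ncol(ppv)), each = length(sizes)),
    ppv = as.numeric(unclass(ppv)),
    method = attr(ppv, "method"),
    measure = attr(ppv, "measure"),
    statistic = attr(ppv, "statistic"),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
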