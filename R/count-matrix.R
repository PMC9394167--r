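#' Aptamer count matrix
#'
#' Container for dereplicated read counts: an integer matrix with one row
#' per aptamer variable-region sequence and one column per sample, plus
#' per-sample totals of processed reads. The totals are the normalization
#' denominator and are carried separately because they count *all*
#' dereplicated reads of a sample, including reads later discarded by the
#' minimum-count filter; they therefore must be at least the column sums.
#'
#' @param counts integer matrix, rownames = uppercase A/C/G/T variable
#'   regions, colnames = sample ids.
#' @param totals per-sample totals (named numeric); defaults to column sums.
#' @return object of class `count_matrix`: a list with elements `counts`
#'   and `totals`.
#' @export
count_matrix <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop_aptashape("count matrix needs sequence rownames and sample colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop_aptashape("duplicate sequence rows: %s",
                   paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                         collapse = ", "))
  if (!all(is_dna(rownames(counts))))
    stop_aptashape("sequence rownames must be uppercase A/C/G/T strings")
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts)))
    stop_aptashape("counts must be non-negative integers")
  csums <- colSums(counts)
  if (is.null(totals)) {
    totals <- csums
  } else {
    totals <- unlist(totals)
    if (is.null(names(totals))) names(totals) <- colnames(counts)
    totals <- totals[colnames(counts)]
    if (anyNA(totals))
      stop_aptashape("totals missing for sample(s): %s",
                     paste(colnames(counts)[is.na(totals)], collapse = ", "))
    low <- colnames(counts)[totals < csums]
    if (length(low))
      stop_aptashape("totals below retained column sums for sample(s): %s",
                     paste(low, collapse = ", "))
  }
  structure(list(counts = counts, totals = totals), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d aptamers x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("totals:", paste(sprintf("%s=%g", names(x$totals), x$totals),
                       collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read an aptamer count table from TSV
#'
#' First column `sequence`, remaining columns one per sample. An optional
#' leading comment row `#total:<TAB>t1<TAB>t2...` carries the per-sample
#' totals of all processed reads; when absent, totals default to the column
#' sums (appropriate for tables that were never count-filtered).
#'
#' @param path file path.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  totals <- NULL
  tot_line <- grep("^#total:", lines)
  if (length(tot_line)) {
    totals_raw <- strsplit(sub("^#total:\t?", "", lines[tot_line[1]]), "\t")[[1]]
    totals <- suppressWarnings(as.numeric(totals_raw))
    if (anyNA(totals))
      stop_aptashape("non-numeric totals row in %s", path)
    lines <- lines[-tot_line]
  }
  df <- read.delim(text = lines, colClasses = "character", check.names = FALSE)
  if (names(df)[1] != "sequence")
    stop_aptashape("first column of %s must be 'sequence'", path)
  seqs <- df$sequence
  if (anyDuplicated(seqs))
    stop_aptashape("duplicate sequence in %s: %s", path,
                   paste(unique(seqs[duplicated(seqs)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- is.na(num) | num != round(num) | num < 0
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop_aptashape("non-integer count '%s' (sequence %s, sample %s) in %s",
                   m[i[1], i[2]], seqs[i[1]], colnames(m)[i[2]], path)
  }
  dimnames(num) <- list(seqs, colnames(m))
  if (!is.null(totals)) {
    if (length(totals) != ncol(num))
      stop_aptashape("totals row in %s has %d values for %d samples",
                     path, length(totals), ncol(num))
    names(totals) <- colnames(num)
  }
  count_matrix(num, totals)
}

#' Write an aptamer count table to TSV
#'
#' Inverse of [read_count_table()]; the per-sample totals are stored in a
#' `#total:` comment row so that the normalization denominator survives the
#' round trip.
#'
#' @param x a [count_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#total:\t", paste(format_num(x$totals), collapse = "\t")), con)
  writeLines(paste(c("sequence", colnames(x$counts)), collapse = "\t"), con)
  if (nrow(x$counts)) {
    body <- apply(x$counts, 1, function(r) paste(format_num(r), collapse = "\t"))
    writeLines(paste(rownames(x$counts), body, sep = "\t"), con)
  }
  invisible(path)
}

# integer-valued doubles without scientific notation
format_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write a frequency (or relative-level) matrix to TSV
#' @param m numeric matrix with sequence rownames and sample colnames.
#' @param path file path.
#' @param value_digits significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_matrix_table <- function(m, path, value_digits = 10) {
  df <- data.frame(sequence = rownames(m),
                   signif(m, value_digits),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a frequency (or relative-level) matrix from TSV
#' @param path file path.
#' @return numeric matrix with sequence rownames.
#' @export
read_matrix_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
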