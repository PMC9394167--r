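#' Construct and validate a sample sheet
#'
#' The sample sheet maps sequencing barcodes onto sample identity, clinical
#' group and cohort. Groups are `C` (control), `Ta` (non-muscle-invasive
#' tumor) and `T2T4` (muscle-invasive tumor); cohorts are `training`
#' (used to fit the regression model) and `validation` (used for
#' classification).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param barcode DNA barcodes, unique and of equal length.
#' @param group group labels, matched case-insensitively onto
#'   `C`, `Ta`, `T2T4` (hyphenated forms such as `"T2-T4"` are accepted).
#' @param cohort `"training"` or `"validation"` (case-insensitive);
#'   defaults to training for every sample.
#' @return a `data.frame` of class `aptashape_sheet` with columns
#'   `sample_id`, `barcode`, `group` (factor with levels C, Ta, T2T4) and
#'   `cohort`.
#' @export
sample_sheet <- function(sample_id, barcode, group,
                         cohort = rep("training", length(sample_id))) {
  sample_id <- as.character(sample_id)
  barcode <- toupper(as.character(barcode))
  n <- length(sample_id)
  if (length(barcode) != n || length(group) != n || length(cohort) != n)
    stop_aptashape("sample sheet columns have unequal lengths")
  if (n == 0) stop_aptashape("sample sheet is empty")
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup))
    stop_aptashape("duplicate sample_id: %s", paste(unique(dup), collapse = ", "))
  dup <- barcode[duplicated(barcode)]
  if (length(dup))
    stop_aptashape("duplicate barcode: %s", paste(unique(dup), collapse = ", "))
  if (length(unique(nchar(barcode))) > 1)
    stop_aptashape("barcodes must all have the same length")
  if (!all(is_dna(barcode)) || any(nchar(barcode) == 0))
    stop_aptashape("barcodes must be non-empty A/C/G/T strings")
  group <- parse_group(group)
  cohort <- parse_cohort(cohort)
  out <- data.frame(
    sample_id = sample_id, barcode = barcode,
    group = group, cohort = cohort,
    stringsAsFactors = FALSE
  )
  class(out) <- c("aptashape_sheet", "data.frame")
  out
}

group_levels <- c("C", "Ta", "T2T4")

parse_group <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(as.character(x)))
  map <- c(c = "C", ta = "Ta", t2t4 = "T2T4")
  bad <- unique(x[is.na(x) | !(key %in% names(map))])
  if (length(bad))
    stop_aptashape("unknown group label(s): %s (expected C, Ta or T2T4)",
                   paste(bad, collapse = ", "))
  factor(unname(map[key]), levels = group_levels)
}

parse_cohort <- function(x) {
  key <- tolower(as.character(x))
  bad <- unique(x[is.na(x) | !(key %in% c("training", "validation"))])
  if (length(bad))
    stop_aptashape("unknown cohort label(s): %s (expected training or validation)",
                   paste(bad, collapse = ", "))
  factor(key, levels = c("training", "validation"))
}

#' Read a sample sheet from TSV
#'
#' Expects a tab-separated file with header columns `sample_id`, `barcode`,
#' `group` and (optionally) `cohort`; missing cohort defaults to training.
#'
#' @param path file path.
#' @return validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "barcode", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_aptashape("sample sheet %s is missing column(s): %s",
                   path, paste(miss, collapse = ", "))
  cohort <- if ("cohort" %in% names(df)) df$cohort else rep("training", nrow(df))
  sample_sheet(df$sample_id, df$barcode, df$group, cohort)
}

#' Write a sample sheet to TSV
#' @param sheet a [sample_sheet()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
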