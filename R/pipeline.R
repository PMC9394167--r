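#' Run the full branched-selection analysis pipeline
#'
#' Orchestrates the three analysis stages: read processing (when FASTQ
#' input is given) into a clustered, filtered, normalized frequency
#' matrix; differential-enrichment testing and discriminatory-aptamer
#' selection on the training cohort; and hierarchical clustering, PCA and
#' sign-rule classification on the validation cohort (the training cohort
#' is used when the sheet contains no validation samples). All result
#' tables are written as TSV files under `out_dir` together with a run log
#' listing the configuration, seed and per-stage statistics; reruns with
#' identical inputs, configuration and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param sheet a [sample_sheet()].
#' @param counts a [count_matrix()], or `NULL` when `fastq1`/`fastq2` are
#'   given.
#' @param fastq1,fastq2 multiplexed mate FASTQ files (alternative input).
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return list with elements `counts` (clustered, filtered),
#'   `frequencies`, `ols` (result table), `discriminatory`, `dendrogram`,
#'   `pca` (per aptamer set), `classification`, `accuracy`.
#' @export
run_pipeline <- function(config, sheet, counts = NULL,
                         fastq1 = NULL, fastq2 = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "aptashape_config"),
            inherits(sheet, "aptashape_sheet"))
  log_lines <- c("# aptashape run log", "", "## config",
                 strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]], "")
  # --- stage: seqproc -------------------------------------------------
  if (is.null(counts)) {
    if (is.null(fastq1) || is.null(fastq2))
      pipeline_abort("seqproc", "either counts or a FASTQ pair is required")
    counts <- fastq_to_counts(fastq1, fastq2, sheet, config)
    st <- attr(counts, "stats")
    log_lines <- c(log_lines, "## seqproc",
                   sprintf("demultiplexed: %s",
                           paste(names(attr(counts, "demux")),
                                 attr(counts, "demux"),
                                 sep = "=", collapse = " ")),
                   sprintf("%s: reads=%d merged=%d extracted=%d",
                           rownames(st), st[, "reads"], st[, "merged"],
                           st[, "extracted"]), "")
  }
  miss <- setdiff(colnames(counts$counts), sheet$sample_id)
  if (length(miss))
    pipeline_abort("seqproc", sprintf(
      "sample(s) in counts but missing from sheet: %s",
      paste(miss, collapse = ", ")))
  n_raw <- nrow(counts$counts)
  filtered <- filter_min_count(counts, config$min_count)
  clustered <- cluster_by_edit_distance(filtered, config$cluster_max_dist)
  freqs <- normalize_frequencies(clustered)
  freqs <- suppressWarnings(select_top_abundant(freqs, config$top_n))
  log_lines <- c(log_lines, "## abundance",
                 sprintf("unique sequences: %d", n_raw),
                 sprintf("after min-count %d filter: %d", config$min_count,
                         nrow(filtered$counts)),
                 sprintf("after clustering (max dist %d): %d",
                         config$cluster_max_dist, nrow(clustered$counts)),
                 sprintf("tested (top %d by mean frequency): %d",
                         config$top_n, nrow(freqs)), "")
  # --- stage: diffenrich ----------------------------------------------
  train <- sheet[sheet$cohort == "training", , drop = FALSE]
  train <- train[train$sample_id %in% colnames(freqs), , drop = FALSE]
  if (nrow(train) < 6)
    pipeline_abort("diffenrich", "training cohort has fewer than 6 samples")
  class(train) <- class(sheet)
  levels_train <- suppressWarnings(
    relative_to_mean(freqs[, train$sample_id, drop = FALSE]))
  ols <- test_differential_enrichment(levels_train, train)
  disc <- select_discriminatory(ols, config)
  log_lines <- c(log_lines, "## diffenrich",
                 sprintf("aptamers tested: %d", nrow(levels_train)),
                 sprintf("discriminatory (aptamer, comparison) pairs: %d",
                         nrow(disc)),
                 sprintf("distinct discriminatory aptamers: %d",
                         length(unique(disc$sequence))), "")
  # --- stage: classify ------------------------------------------------
  val <- sheet[sheet$cohort == "validation", , drop = FALSE]
  val <- val[val$sample_id %in% colnames(freqs), , drop = FALSE]
  cohort_name <- "validation"
  if (nrow(val) == 0) {
    val <- train
    cohort_name <- "training"
  }
  class(val) <- class(sheet)
  classify_out <- NULL
  if (nrow(disc) > 0) {
    classify_out <- tryCatch(
      classify_cohort(freqs, val, disc),
      error = function(e) {
        pipeline_abort("classify", conditionMessage(e))
      })
    log_lines <- c(log_lines, "## classify",
                   sprintf("cohort: %s (%d samples)", cohort_name, nrow(val)),
                   sprintf("%s accuracy: %.4f",
                           names(classify_out$accuracy),
                           classify_out$accuracy), "")
  } else {
    log_lines <- c(log_lines, "## classify",
                   "skipped: no discriminatory aptamers selected", "")
  }
  result <- list(counts = clustered, frequencies = freqs, ols = ols,
                 discriminatory = disc,
                 dendrogram = classify_out$dendrogram,
                 pca = classify_out$pca,
                 classification = classify_out$classification,
                 accuracy = classify_out$accuracy,
                 log = log_lines)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

pipeline_abort <- function(stage, msg) {
  stop_aptashape("[stage %s] %s", stage, msg)
}

# Validation-cohort analysis on the discriminatory aptamers: relative
# levels within the cohort, heatmap column clustering, per-set PCA with
# sign-rule classification. Only aptamers observed in every cohort sample
# enter: the validation analysis presumes the discriminatory aptamers are
# present in the cohort's selections, and an aptamer at its detection
# limit has a quasi-binary dropout profile that would swamp the PCA with
# presence/absence variance unrelated to group.
classify_cohort <- function(freqs, sheet, disc) {
  present <- intersect(unique(disc$sequence), rownames(freqs))
  if (length(present)) {
    in_all <- present[apply(freqs[present, sheet$sample_id, drop = FALSE] > 0,
                            1, all)]
    if (length(in_all)) present <- in_all
  }
  if (!length(present))
    stop_aptashape("no discriminatory aptamer present in the cohort matrix")
  levels <- suppressWarnings(
    relative_to_mean(freqs[present, sheet$sample_id, drop = FALSE]))
  # rows ordered by family label then sequence (heatmap convention)
  fam <- disc$family[match(rownames(levels), disc$sequence)]
  levels <- levels[order(is.na(fam), fam, rownames(levels)), , drop = FALSE]
  dend <- hierarchical_cluster_columns(levels)
  sets <- list(
    vs_control = unique(disc$sequence[disc$comparison %in%
                                        c("Ta_vs_C", "T2T4_vs_C")]),
    stage = unique(disc$sequence[disc$comparison == "T2T4_vs_Ta"]),
    combined = unique(disc$sequence)
  )
  pca <- list()
  cls <- list()
  for (nm in names(sets)) {
    seqs <- intersect(sets[[nm]], rownames(levels))
    if (length(seqs) < 1) next
    x <- t(levels[seqs, , drop = FALSE])
    p <- tryCatch(pca_fit(x), error = function(e) NULL)
    if (is.null(p)) next
    p <- orient_components(p, sheet)
    pca[[nm]] <- p
    mode <- switch(nm,
                   vs_control = "cancer_vs_control",
                   stage = "Ta_vs_T2T4",
                   combined = "combined")
    if (mode == "Ta_vs_T2T4" &&
        (ncol(p$scores) < 2 || !any(sheet$group != "C"))) next
    cls[[nm]] <- tryCatch(classify_by_sign(p, sheet, mode),
                          error = function(e) NULL)
  }
  classification <- do.call(rbind, lapply(names(cls), function(nm) {
    d <- as.data.frame(cls[[nm]])
    d$aptamer_set <- nm
    d
  }))
  acc <- unlist(lapply(names(cls), function(nm) {
    a <- attr(cls[[nm]], "accuracy")
    stats::setNames(a, paste0(nm, ".", names(a)))
  }))
  list(levels = levels, dendrogram = dend, pca = pca,
       classification = classification, accuracy = acc)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(result$counts, file.path(out_dir, "counts_clustered.tsv"))
  write_matrix_table(result$frequencies, file.path(out_dir, "frequencies.tsv"))
  write_tsv_round(result$ols, file.path(out_dir, "ols_results.tsv"))
  write_tsv_round(as.data.frame(result$discriminatory),
                  file.path(out_dir, "discriminatory.tsv"))
  for (cmp in unique(result$ols$comparison)) {
    d <- result$ols[result$ols$comparison == cmp, ]
    vol <- data.frame(sequence = d$sequence, beta = d$beta,
                      neg_log10_adj_p = -log10(pmax(d$adj_p, 1e-300)))
    write_tsv_round(vol, file.path(out_dir, paste0("volcano_", cmp, ".tsv")))
  }
  if (!is.null(result$dendrogram))
    writeLines(result$dendrogram$newick, file.path(out_dir, "dendrogram.nwk"))
  for (nm in names(result$pca)) {
    p <- result$pca[[nm]]
    sc <- data.frame(sample_id = rownames(p$scores),
                     signif(p$scores, 10), check.names = FALSE)
    write_tsv_round(sc, file.path(out_dir, paste0("pca_scores_", nm, ".tsv")))
    vf <- data.frame(component = paste0("PC", seq_along(p$var_frac)),
                     variance_fraction = signif(p$var_frac, 10))
    write_tsv_round(vf, file.path(out_dir, paste0("pca_variance_", nm, ".tsv")))
    ld <- data.frame(sequence = rownames(p$loadings),
                     signif(p$loadings, 10), check.names = FALSE)
    write_tsv_round(ld, file.path(out_dir, paste0("pca_loadings_", nm, ".tsv")))
  }
  if (!is.null(result$classification))
    write_tsv_round(result$classification,
                    file.path(out_dir, "predictions.tsv"))
  if (!is.null(result$accuracy)) {
    acc <- data.frame(task = names(result$accuracy),
                      accuracy = signif(unname(result$accuracy), 10))
    write_tsv_round(acc, file.path(out_dir, "accuracy.tsv"))
  }
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

write_tsv_round <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
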