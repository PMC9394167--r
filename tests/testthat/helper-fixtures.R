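# Small reusable fixtures, built in code.

tiny_sheet <- function() {
  sample_sheet(
    sample_id = c("c1", "c2", "t1", "t2", "m1", "m2"),
    barcode = c("AAGG", "CCTT", "GGAA", "TTCC", "ACAC", "GTGT"),
    group = c("C", "C", "Ta", "Ta", "T2T4", "T2T4")
  )
}

tiny_counts <- function() {
  m <- matrix(c(10, 8, 2, 0,
                5, 6, 0, 3,
                1, 0, 4, 4,
                0, 2, 6, 5,
                7, 7, 7, 7,
                3, 3, 3, 3),
              nrow = 4, ncol = 6,
              dimnames = list(c("AAAA", "CCCC", "GGGG", "TTTT"),
                              c("c1", "c2", "t1", "t2", "m1", "m2")))
  count_matrix(m)
}

# moderate two-cohort study used by pipeline-level tests: big enough for
# reliable effect recovery, small enough to run in seconds
moderate_study <- function(seed = 11L, depth = 50000L) {
  cfg <- simulation_config(
    n_families = 20L, members_per_family = 3L, n_singletons = 140L,
    read_depth = depth, n_per_group = c(C = 16L, Ta = 16L, T2T4 = 16L),
    sample_noise_sigma = 0.3, seed = seed
  )
  simulate_study(cfg, n_validation_per_group = c(C = 8L, Ta = 6L, T2T4 = 4L),
                 n_vs_c = 3L, n_stage = 3L,
                 multiplier_vs_c = 0.5, multiplier_stage = 2)
}

# planted effect units (one per planted family/singleton) with the
# comparisons they should trigger
planted_units <- function(truth) {
  rows <- which(truth$planted)
  key <- ifelse(is.na(truth$family[rows]), paste0("row", rows),
                truth$family[rows])
  split(rows, key)
}

# map selected cluster centroids back to truth rows via cluster membership
selection_hits_planted <- function(disc, clustered, truth) {
  members <- attr(clustered, "members")
  unit <- planted_units(truth)
  cmp_of_unit <- vapply(unit, function(rows) {
    if (any(truth$mult_Ta[rows] != truth$mult_T2T4[rows])) "Ta_vs_T2T4"
    else "vsC_cancer"
  }, character(1))
  planted_seqs <- truth$sequence[truth$planted]
  cluster_of <- function(seqs) {
    members$centroid[match(seqs, members$sequence)]
  }
  planted_centroids <- unique(cluster_of(planted_seqs))
  recovered <- vapply(names(unit), function(k) {
    cents <- unique(cluster_of(truth$sequence[unit[[k]]]))
    want <- if (cmp_of_unit[k] == "vsC_cancer")
      c("Ta_vs_C", "T2T4_vs_C") else "T2T4_vs_Ta"
    any(disc$sequence %in% cents & disc$comparison %in% want)
  }, logical(1))
  false_pos <- setdiff(unique(disc$sequence), planted_centroids)
  list(recovered = recovered, n_false_positive = length(false_pos))
}

# run the count-level analysis stages (filter, cluster, normalize, top-n,
# relative levels, OLS, selection) on a training cohort
run_diffenrich <- function(counts, sheet, cfg = pipeline_config(top_n = 1000L)) {
  filtered <- filter_min_count(counts, cfg$min_count)
  clustered <- cluster_by_edit_distance(filtered, cfg$cluster_max_dist)
  freqs <- normalize_frequencies(clustered)
  freqs <- suppressWarnings(select_top_abundant(freqs, cfg$top_n))
  train <- sheet[sheet$cohort == "training", , drop = FALSE]
  class(train) <- class(sheet)
  lv <- suppressWarnings(relative_to_mean(freqs[, train$sample_id, drop = FALSE]))
  ols <- test_differential_enrichment(lv, train)
  list(clustered = clustered, freqs = freqs, ols = ols,
       disc = select_discriminatory(ols, cfg))
}
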