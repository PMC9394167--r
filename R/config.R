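#' Pipeline configuration
#'
#' Collects the tunable thresholds of the analysis. Defaults follow the
#' branched-selection study design this package implements: sequences kept
#' when observed at least 4 times in a sample; near-identical reads merged
#' at optimal-string-alignment distance < 4 (`cluster_max_dist = 3`); the
#' 1000 most abundant clustered aptamers tested; an aptamer is called
#' discriminatory when its group regression coefficient exceeds 0.5 in
#' magnitude (tumor group vs control) or 0.25 (late vs early stage) with a
#' Benjamini-Hochberg adjusted p-value below 0.01.
#'
#' @param min_count minimum per-sample observation count (default 4).
#' @param cluster_max_dist maximum edit distance for read clustering
#'   (default 3, i.e. distance < 4).
#' @param top_n number of most abundant aptamers carried into testing
#'   (default 1000).
#' @param coef_threshold_vs_C minimum |coefficient| for the Ta-vs-C and
#'   T2T4-vs-C comparisons (default 0.5, relative-level units).
#' @param coef_threshold_Ta_vs_T2T4 minimum |coefficient| for the
#'   T2T4-vs-Ta comparison (default 0.25).
#' @param adj_p_threshold adjusted-p significance gate (default 0.01).
#' @param family_max_dist single-linkage edit-distance threshold for
#'   sequence-family grouping of discriminatory aptamers (default 8).
#' @param flank5,flank3 constant regions flanking the variable region in
#'   the merged amplicon orientation.
#' @param max_barcode_mismatch,max_flank_mismatch,min_overlap,max_mismatch_frac
#'   read-processing tolerances (see [demultiplex()], [join_pairs()],
#'   [extract_variable_region()]).
#' @param length_range admissible variable-region length (default 30..42,
#'   centered on the designed 36).
#' @param rng_seed integer seed from which all pipeline randomness derives.
#' @return list of class `aptashape_config`.
#' @export
pipeline_config <- function(min_count = 4L,
                            cluster_max_dist = 3L,
                            top_n = 1000L,
                            coef_threshold_vs_C = 0.5,
                            coef_threshold_Ta_vs_T2T4 = 0.25,
                            adj_p_threshold = 0.01,
                            family_max_dist = 8L,
                            flank5 = "GGGGCCACCAACGACATT",
                            flank3 = "GTTGATATAAATAGTGCCCATGGATC",
                            max_barcode_mismatch = 0L,
                            max_flank_mismatch = 1L,
                            min_overlap = 10L,
                            max_mismatch_frac = 0.1,
                            length_range = c(30L, 42L),
                            rng_seed = 1L) {
  cfg <- list(
    min_count = as.integer(min_count),
    cluster_max_dist = as.integer(cluster_max_dist),
    top_n = as.integer(top_n),
    coef_threshold_vs_C = as.numeric(coef_threshold_vs_C),
    coef_threshold_Ta_vs_T2T4 = as.numeric(coef_threshold_Ta_vs_T2T4),
    adj_p_threshold = as.numeric(adj_p_threshold),
    family_max_dist = as.integer(family_max_dist),
    flank5 = toupper(flank5),
    flank3 = toupper(flank3),
    max_barcode_mismatch = as.integer(max_barcode_mismatch),
    max_flank_mismatch = as.integer(max_flank_mismatch),
    min_overlap = as.integer(min_overlap),
    max_mismatch_frac = as.numeric(max_mismatch_frac),
    length_range = as.integer(length_range),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "aptashape_config")
}

validate_config <- function(cfg) {
  if (cfg$min_count < 1) stop_aptashape("min_count must be >= 1")
  if (cfg$top_n < 1) stop_aptashape("top_n must be >= 1")
  if (cfg$cluster_max_dist < 0) stop_aptashape("cluster_max_dist must be >= 0")
  for (f in c("coef_threshold_vs_C", "coef_threshold_Ta_vs_T2T4",
              "adj_p_threshold"))
    if (cfg[[f]] <= 0) stop_aptashape("%s must be > 0", f)
  if (!is_dna(cfg$flank5) || !is_dna(cfg$flank3) ||
      !nzchar(cfg$flank5) || !nzchar(cfg$flank3))
    stop_aptashape("flank5/flank3 must be non-empty A/C/G/T strings")
  if (length(cfg$length_range) != 2 || cfg$length_range[1] > cfg$length_range[2])
    stop_aptashape("length_range must be an increasing pair")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys are [pipeline_config()] arguments.
#' @return an `aptashape_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_aptashape("unknown config key(s) in %s: %s", path,
                   paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param cfg an `aptashape_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# seeds for pipeline sub-stages, derived from a single base seed so that
# no stage perturbs another's stream; kept within 32-bit integer range
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + tag) %% .Machine$integer.max)
}
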