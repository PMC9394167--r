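#' Configuration for the branched-selection simulator
#'
#' The simulator emulates the statistical structure of a branched selection
#' read out by sequencing: a pool of variable-region sequences organised
#' into families of point-mutated ancestors plus unrelated singletons;
#' heavy-tailed baseline pool fractions (log-normal, calibrated so that the
#' most abundant aptamer holds roughly 10% of the pool while the vast
#' majority individually stay below 1%); group-specific multiplicative
#' enrichment or depletion for a planted subset of aptamers; multiplicative
#' log-normal per-sample noise representing patient-to-patient variability;
#' and multinomial sequencing at a configurable depth.
#'
#' @param n_families number of mutational families.
#' @param members_per_family sequences per family (ancestor included).
#' @param n_singletons unrelated sequences.
#' @param variable_region_length length of the randomized region (36 by
#'   design of the pool oligo).
#' @param mutation_rate_within_family per-nucleotide substitution
#'   probability applied independently to each family member relative to
#'   its ancestor.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   baseline pool fractions before normalization. The default
#'   `sdlog = 2` reproduces the observed pool shape (top aptamer around
#'   10% of reads, >90% of aptamers individually under 1%).
#' @param sample_noise_sigma sdlog of the multiplicative per-aptamer,
#'   per-sample log-normal noise (0 disables noise).
#' @param read_depth multinomial reads per sample. The default
#'   100,000 keeps simulated studies tractable; real branched selections
#'   average several million reads per sample and behave identically up to
#'   sampling noise.
#' @param n_per_group named integer vector of samples per group
#'   (names C, Ta, T2T4).
#' @param flank5,flank3 constant regions used when emitting reads.
#' @param barcode_length,read_length,phred_quality,error_rate read-emission
#'   parameters: barcode length, length of each mate, constant Phred
#'   quality, and an optional uniform per-base substitution error rate.
#' @param seed integer; all simulator randomness derives from it.
#' @return list of class `aptashape_simconfig`.
#' @export
simulation_config <- function(n_families = 50L,
                              members_per_family = 4L,
                              n_singletons = 300L,
                              variable_region_length = 36L,
                              mutation_rate_within_family = 0.1,
                              abundance_meanlog = 0,
                              abundance_sdlog = 2,
                              sample_noise_sigma = 0.3,
                              read_depth = 100000L,
                              n_per_group = c(C = 32L, Ta = 32L, T2T4 = 32L),
                              flank5 = "GGGGCCACCAACGACATT",
                              flank3 = "GTTGATATAAATAGTGCCCATGGATC",
                              barcode_length = 6L,
                              read_length = 75L,
                              phred_quality = 37L,
                              error_rate = 0,
                              seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    members_per_family = as.integer(members_per_family),
    n_singletons = as.integer(n_singletons),
    variable_region_length = as.integer(variable_region_length),
    mutation_rate_within_family = as.numeric(mutation_rate_within_family),
    abundance_meanlog = as.numeric(abundance_meanlog),
    abundance_sdlog = as.numeric(abundance_sdlog),
    sample_noise_sigma = as.numeric(sample_noise_sigma),
    read_depth = as.integer(read_depth),
    n_per_group = n_per_group,
    flank5 = toupper(flank5),
    flank3 = toupper(flank3),
    barcode_length = as.integer(barcode_length),
    read_length = as.integer(read_length),
    phred_quality = as.integer(phred_quality),
    error_rate = as.numeric(error_rate),
    seed = as.integer(seed)
  )
  if (cfg$read_depth < 1) stop_aptashape("read_depth must be >= 1")
  if (cfg$mutation_rate_within_family < 0 || cfg$mutation_rate_within_family >= 1)
    stop_aptashape("mutation_rate_within_family must be in [0, 1)")
  if (cfg$sample_noise_sigma < 0) stop_aptashape("sample_noise_sigma must be >= 0")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop_aptashape("error_rate must be in [0, 1)")
  if (any(cfg$n_per_group < 0)) stop_aptashape("n_per_group must be >= 0")
  structure(cfg, class = "aptashape_simconfig")
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

mutate_sequences <- function(seqs, rate) {
  if (rate == 0 || !length(seqs)) return(seqs)
  chars <- strsplit(seqs, "")
  vapply(chars, function(ch) {
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      # substitute with one of the three other bases
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
}

#' Generate a simulated aptamer pool with ground truth
#'
#' Ancestor sequences are drawn uniformly over the 4^L sequence space;
#' family members carry i.i.d. point substitutions relative to their
#' ancestor; baseline pool fractions are drawn log-normal and normalized to
#' sum to one. All group multipliers start at 1; planted effects are added
#' afterwards with [plant_effects()] or [auto_plant()].
#'
#' @param cfg a [simulation_config()].
#' @return the truth table: a `data.frame` with columns `sequence`,
#'   `family` (`NA` for singletons), `baseline` (fractions summing to 1)
#'   and multiplier columns `mult_C`, `mult_Ta`, `mult_T2T4`.
#' @export
generate_pool <- function(cfg) {
  n_total <- cfg$n_families * cfg$members_per_family + cfg$n_singletons
  if (n_total < 1) stop_aptashape("empty pool requested")
  if (log(n_total) > cfg$variable_region_length * log(4))
    stop_aptashape("pool of %d sequences exceeds 4^%d distinct sequences",
                   n_total, cfg$variable_region_length)
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    seqs <- character(0)
    fam <- character(0)
    if (cfg$n_families > 0) {
      ancestors <- random_dna(cfg$n_families, cfg$variable_region_length)
      for (f in seq_len(cfg$n_families)) {
        members <- c(ancestors[f],
                     mutate_sequences(rep(ancestors[f],
                                          cfg$members_per_family - 1L),
                                      cfg$mutation_rate_within_family))
        seqs <- c(seqs, members)
        fam <- c(fam, rep(sprintf("F%03d", f), length(members)))
      }
    }
    if (cfg$n_singletons > 0) {
      seqs <- c(seqs, random_dna(cfg$n_singletons, cfg$variable_region_length))
      fam <- c(fam, rep(NA_character_, cfg$n_singletons))
    }
    # resolve accidental duplicates by redrawing (vanishingly rare at L=36)
    for (tries in 1:100) {
      dup <- duplicated(seqs)
      if (!any(dup)) break
      seqs[dup] <- random_dna(sum(dup), cfg$variable_region_length)
    }
    if (anyDuplicated(seqs))
      stop_aptashape("could not generate %d distinct sequences", n_total)
    x <- rlnorm(n_total, cfg$abundance_meanlog, cfg$abundance_sdlog)
    truth <- data.frame(
      sequence = seqs, family = fam, baseline = x / sum(x),
      mult_C = 1, mult_Ta = 1, mult_T2T4 = 1,
      stringsAsFactors = FALSE
    )
    truth
  })
}

#' Plant group-specific enrichment effects into a truth table
#'
#' Effects are expressed as multiplicative changes of an aptamer's
#' selection propensity in specific groups: comparison `vsC_cancer`
#' multiplies both tumor groups (Ta and T2T4) relative to control;
#' comparison `Ta_vs_T2T4` splits the multiplier symmetrically about
#' control (Ta times `1/sqrt(m)`, T2T4 times `sqrt(m)`, so the
#' T2T4-to-Ta propensity ratio is `m` while neither stage moves far from
#' control). The symmetric split mirrors the observed structure of
#' stage-discriminating aptamers, which separate early from late stage
#' without passing the versus-control selection thresholds. Because
#' same-family sequences model reads of a common ancestor that bind the
#' same target, an effect planted on a family member is applied to the
#' whole family.
#'
#' @param truth a truth table from [generate_pool()].
#' @param effects `data.frame` with columns `index` (row in `truth`),
#'   `comparison` (`"vsC_cancer"` or `"Ta_vs_T2T4"`) and `multiplier` (> 0).
#' @return the truth table with updated multiplier columns and a logical
#'   `planted` column.
#' @export
plant_effects <- function(truth, effects) {
  if (is.null(truth$planted)) truth$planted <- FALSE
  if (is.null(effects) || nrow(effects) == 0) return(truth)
  stopifnot(all(c("index", "comparison", "multiplier") %in% names(effects)))
  if (any(effects$multiplier <= 0)) stop_aptashape("multipliers must be > 0")
  bad <- setdiff(effects$comparison, c("vsC_cancer", "Ta_vs_T2T4"))
  if (length(bad))
    stop_aptashape("unknown comparison(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(effects$index))
    stop_aptashape("each aptamer may carry at most one planted effect")
  for (k in seq_len(nrow(effects))) {
    i <- effects$index[k]
    rows <- if (!is.na(truth$family[i]))
      which(truth$family == truth$family[i]) else i
    if (any(truth$planted[rows]))
      stop_aptashape("planted effects overlap at truth row %d", i)
    m <- effects$multiplier[k]
    if (effects$comparison[k] == "vsC_cancer") {
      truth$mult_Ta[rows] <- truth$mult_Ta[rows] * m
      truth$mult_T2T4[rows] <- truth$mult_T2T4[rows] * m
    } else {
      truth$mult_Ta[rows] <- truth$mult_Ta[rows] / sqrt(m)
      truth$mult_T2T4[rows] <- truth$mult_T2T4[rows] * sqrt(m)
    }
    truth$planted[rows] <- TRUE
  }
  truth
}

#' Randomly place planted effects on detectable aptamers
#'
#' Convenience wrapper around [plant_effects()]: picks aptamers at random
#' among those abundant enough to be observed at the simulated depth
#' (baseline fraction at least `min_fraction`), at most one per family,
#' and plants depletion-in-cancer effects and late-stage enrichment
#' effects.
#'
#' @param truth truth table from [generate_pool()].
#' @param n_vs_c number of aptamers depleted/enriched in both tumor groups.
#' @param n_stage number of aptamers changed in T2T4 relative to Ta.
#' @param multiplier_vs_c multiplier for the `vsC_cancer` effects
#'   (default 0.5, i.e. depleted in cancer).
#' @param multiplier_stage multiplier for the `Ta_vs_T2T4` effects
#'   (default 2, i.e. enriched late stage).
#' @param min_fraction detectability floor on the baseline pool fraction.
#' @param seed integer seed for the placement.
#' @return truth table with effects planted.
#' @export
auto_plant <- function(truth, n_vs_c = 5L, n_stage = 5L,
                       multiplier_vs_c = 0.5, multiplier_stage = 2,
                       min_fraction = 1e-4, seed = 1L) {
  withr::with_seed(derive_seed(seed, 3L), {
    eligible <- which(truth$baseline >= min_fraction)
    # at most one candidate per family
    fam_key <- ifelse(is.na(truth$family[eligible]),
                      paste0("s", eligible), truth$family[eligible])
    eligible <- eligible[!duplicated(fam_key)]
    need <- n_vs_c + n_stage
    if (length(eligible) < need)
      stop_aptashape("only %d aptamers above min_fraction; %d needed",
                     length(eligible), need)
    pick <- sample(eligible, need)
    effects <- data.frame(
      index = pick,
      comparison = rep(c("vsC_cancer", "Ta_vs_T2T4"), c(n_vs_c, n_stage)),
      multiplier = rep(c(multiplier_vs_c, multiplier_stage),
                       c(n_vs_c, n_stage))
    )
    plant_effects(truth, effects)
  })
}

#' Generate a sample sheet for a simulated study
#'
#' @param cfg a [simulation_config()] (group sizes and barcode length).
#' @param cohort cohort label for all samples.
#' @param prefix prefix for the sample ids.
#' @param barcode_offset skip this many barcodes before assigning (use to
#'   give two cohorts disjoint barcodes).
#' @return a [sample_sheet()].
#' @export
sim_sample_sheet <- function(cfg, cohort = "training", prefix = cohort,
                             barcode_offset = 0L) {
  npg <- cfg$n_per_group
  if (is.null(names(npg))) names(npg) <- group_levels
  groups <- rep(names(npg), npg)
  n <- length(groups)
  ids <- sprintf("%s_%s_%02d", prefix, groups,
                 unlist(lapply(npg, seq_len)))
  barcodes <- enumerate_barcodes(n, cfg$barcode_length, barcode_offset)
  sample_sheet(ids, barcodes, groups, rep(cohort, n))
}

# deterministic enumeration of distinct DNA barcodes of a given length
enumerate_barcodes <- function(n, len, offset = 0L) {
  if (n + offset > 4^len)
    stop_aptashape("cannot enumerate %d distinct barcodes of length %d",
                   n + offset, len)
  idx <- seq_len(n) - 1L + offset
  vapply(idx, function(i) {
    digits <- integer(len)
    for (p in len:1) {
      digits[p] <- i %% 4L
      i <- i %/% 4L
    }
    paste(DNA_BASES[digits + 1L], collapse = "")
  }, character(1))
}

#' Simulate branched-selection counts for a cohort
#'
#' For sample `s` in group `g`, the sampling propensity of aptamer `a` is
#' `baseline_a * multiplier_{a,g} * eps_{a,s}` with `eps` log-normal
#' (`meanlog` 0, `sdlog = sample_noise_sigma`); the propensities are
#' normalized within the sample and counts drawn
#' Multinomial(`read_depth`, p). Per-sample totals equal the read depth.
#'
#' @param truth truth table from [generate_pool()] / [plant_effects()].
#' @param sheet a [sample_sheet()] for the cohort.
#' @param cfg the [simulation_config()].
#' @return list with elements `counts` (a [count_matrix()]) and
#'   `expected_freq` (matrix of expected percent-of-pool values given the
#'   realized noise).
#' @export
simulate_branched_counts <- function(truth, sheet, cfg) {
  stopifnot(inherits(sheet, "aptashape_sheet"))
  n <- nrow(truth)
  mult <- as.matrix(truth[, c("mult_C", "mult_Ta", "mult_T2T4")])
  colnames(mult) <- group_levels
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    counts <- matrix(0, n, nrow(sheet),
                     dimnames = list(truth$sequence, sheet$sample_id))
    efreq <- counts
    for (s in seq_len(nrow(sheet))) {
      g <- as.character(sheet$group[s])
      w <- truth$baseline * mult[, g]
      if (cfg$sample_noise_sigma > 0)
        w <- w * rlnorm(n, 0, cfg$sample_noise_sigma)
      p <- w / sum(w)
      counts[, s] <- rmultinom(1, cfg$read_depth, p)
      efreq[, s] <- p * 100
    }
    totals <- stats::setNames(rep(cfg$read_depth, nrow(sheet)),
                              sheet$sample_id)
    list(counts = count_matrix(counts, totals), expected_freq = efreq)
  })
}

#' Emit simulated counts as barcoded paired-end FASTQ
#'
#' Each counted molecule becomes one read pair over the amplicon
#' `barcode + flank5 + variable region + flank3`: read 1 is the first
#' `read_length` bases, read 2 the reverse complement of the last
#' `read_length` bases (or the full amplicon when shorter), so the mates
#' overlap in the middle. Qualities are constant at `phred_quality`; an
#' optional uniform substitution error can be applied to exercise the
#' merge and flank-matching tolerances.
#'
#' @param counts a [count_matrix()] (samples must appear in `sheet`).
#' @param sheet a [sample_sheet()] providing barcodes.
#' @param cfg the [simulation_config()].
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<stem>_R1.fastq`, `<stem>_R2.fastq`.
#' @return named character vector with the two file paths.
#' @export
write_fastq_pairs <- function(counts, sheet, cfg, dir, basename = "reads") {
  stopifnot(inherits(counts, "count_matrix"), inherits(sheet, "aptashape_sheet"))
  miss <- setdiff(colnames(counts$counts), sheet$sample_id)
  if (length(miss))
    stop_aptashape("sample(s) not in sheet: %s", paste(miss, collapse = ", "))
  bclen <- unique(nchar(sheet$barcode))
  if (cfg$read_length < bclen + nchar(cfg$flank5))
    stop_aptashape("read_length %d shorter than barcode + 5' flank (%d)",
                   cfg$read_length, bclen + nchar(cfg$flank5))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r1_all <- character(0); r2_all <- character(0); ids_all <- character(0)
  for (s in colnames(counts$counts)) {
    cnt <- counts$counts[, s]
    keep <- cnt > 0
    if (!any(keep)) next
    bc <- sheet$barcode[match(s, sheet$sample_id)]
    amplicon <- paste0(bc, cfg$flank5, rownames(counts$counts)[keep], cfg$flank3)
    amplicon <- rep(amplicon, cnt[keep])
    len <- nchar(amplicon)
    rl <- pmin(cfg$read_length, len)
    r1 <- substr(amplicon, 1, rl)
    r2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substr(amplicon, len - rl + 1, len))))
    ids <- sprintf("%s:%07d", s, seq_along(amplicon))
    r1_all <- c(r1_all, r1); r2_all <- c(r2_all, r2); ids_all <- c(ids_all, ids)
  }
  if (cfg$error_rate > 0) {
    withr::with_seed(derive_seed(cfg$seed, 4L), {
      r1_all <- mutate_sequences(r1_all, cfg$error_rate)
      r2_all <- mutate_sequences(r2_all, cfg$error_rate)
    })
  }
  qchar <- rawToChar(as.raw(33L + cfg$phred_quality))
  paths <- c(R1 = file.path(dir, paste0(basename, "_R1.fastq")),
             R2 = file.path(dir, paste0(basename, "_R2.fastq")))
  for (mate in c("R1", "R2")) {
    seqs <- if (mate == "R1") r1_all else r2_all
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids_all
    quals <- Biostrings::BStringSet(strrep(qchar, nchar(seqs)))
    Biostrings::writeXStringSet(x, paths[[mate]], format = "fastq",
                                qualities = quals)
  }
  paths
}

#' Simulate a complete two-cohort branched-selection study
#'
#' Generates one aptamer pool with planted effects, a training cohort of
#' `cfg$n_per_group` samples and an independent validation cohort drawn
#' from the same pool, mirroring the two-cohort design the analysis
#' expects (fit on training, classify validation). The validation cohort
#' uses its own noise and sampling randomness derived from the same base
#' seed.
#'
#' @param cfg a [simulation_config()] (training-cohort sizes).
#' @param n_validation_per_group named vector of validation group sizes;
#'   the default (10 C, 8 Ta, 4 T2T4) mirrors a small confirmatory cohort.
#' @param n_vs_c,n_stage,multiplier_vs_c,multiplier_stage,min_fraction
#'   planted-effect layout passed to [auto_plant()]; set `n_vs_c` and
#'   `n_stage` to 0 for a null study.
#' @return list with `truth`, `sheet` (both cohorts) and `counts`
#'   (a [count_matrix()] over all samples).
#' @export
simulate_study <- function(cfg,
                           n_validation_per_group = c(C = 10L, Ta = 8L,
                                                      T2T4 = 4L),
                           n_vs_c = 5L, n_stage = 5L,
                           multiplier_vs_c = 0.5, multiplier_stage = 2,
                           min_fraction = 1e-4) {
  truth <- generate_pool(cfg)
  if (n_vs_c + n_stage > 0)
    truth <- auto_plant(truth, n_vs_c, n_stage, multiplier_vs_c,
                        multiplier_stage, min_fraction, seed = cfg$seed)
  else
    truth$planted <- FALSE
  sheet_tr <- sim_sample_sheet(cfg, "training", "tr")
  vcfg <- cfg
  vcfg$n_per_group <- n_validation_per_group
  vcfg$seed <- derive_seed(cfg$seed, 5L)
  sheet_va <- sim_sample_sheet(vcfg, "validation", "va",
                               barcode_offset = nrow(sheet_tr))
  sim_tr <- simulate_branched_counts(truth, sheet_tr, cfg)
  sim_va <- simulate_branched_counts(truth, sheet_va, vcfg)
  sheet <- sample_sheet(c(sheet_tr$sample_id, sheet_va$sample_id),
                        c(sheet_tr$barcode, sheet_va$barcode),
                        c(as.character(sheet_tr$group),
                          as.character(sheet_va$group)),
                        c(as.character(sheet_tr$cohort),
                          as.character(sheet_va$cohort)))
  counts <- count_matrix(cbind(sim_tr$counts$counts, sim_va$counts$counts),
                         c(sim_tr$counts$totals, sim_va$counts$totals))
  list(truth = truth, sheet = sheet, counts = counts)
}
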