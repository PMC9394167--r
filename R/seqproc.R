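#' Demultiplex read pairs by barcode prefix
#'
#' Each read 1 is assigned to the unique barcode whose Hamming distance to
#' its prefix is at most `max_mismatch`; reads matching no barcode, or more
#' than one, are left unassigned. Barcode sets in which two barcodes lie
#' within `2 * max_mismatch` of each other are rejected outright since
#' assignment would be ambiguous by construction.
#'
#' @param read1 character vector (or `DNAStringSet`) of forward reads; the
#'   barcode is their prefix.
#' @param sheet a [sample_sheet()].
#' @param max_mismatch maximum Hamming mismatches tolerated (default 0).
#' @return list with `assignment` (factor of sample ids, `NA` = discarded)
#'   and `stats` (assigned / unassigned / ambiguous counts).
#' @export
demultiplex <- function(read1, sheet, max_mismatch = 0L) {
  stopifnot(inherits(sheet, "aptashape_sheet"))
  read1 <- as.character(read1)
  bc <- sheet$barcode
  blen <- nchar(bc[1])
  if (max_mismatch > 0) {
    bd <- barcode_hamming_matrix(bc)
    diag(bd) <- NA
    if (any(bd <= 2 * max_mismatch, na.rm = TRUE))
      stop_aptashape("barcodes closer than 2*max_mismatch: ambiguity unavoidable")
  }
  prefix <- substr(read1, 1, blen)
  short <- nchar(read1) < blen
  if (max_mismatch == 0) {
    idx <- match(prefix, bc)
    n_amb <- 0L
  } else {
    mm <- vapply(bc, function(b) hamming_to(prefix, b), integer(length(prefix)))
    if (length(prefix) == 1) mm <- matrix(mm, nrow = 1)
    hits <- mm <= max_mismatch
    nhits <- rowSums(hits)
    idx <- ifelse(nhits == 1, max.col(hits, ties.method = "first"), NA_integer_)
    n_amb <- sum(nhits > 1)
  }
  idx[short] <- NA_integer_
  assignment <- factor(sheet$sample_id[idx], levels = sheet$sample_id)
  list(
    assignment = assignment,
    stats = c(assigned = sum(!is.na(assignment)),
              unassigned = sum(is.na(assignment)) - n_amb,
              ambiguous = n_amb)
  )
}

hamming_to <- function(strings, ref) {
  refc <- strsplit(ref, "")[[1]]
  m <- matrix(unlist(strsplit(strings, ""), use.names = FALSE),
              nrow = length(refc))
  as.integer(colSums(m != refc))
}

barcode_hamming_matrix <- function(bc) {
  n <- length(bc)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) d[, i] <- hamming_to(bc, bc[i])
  d
}

#' Join paired-end mates into a merged amplicon sequence
#'
#' Read 2 is reverse-complemented and slid along read 1; among offsets with
#' at least `min_overlap` overlapping bases, the one minimising the number
#' of mismatches wins (ties broken toward the larger overlap). The pair is
#' rejected when the best overlap's mismatch fraction exceeds
#' `max_mismatch_frac`. Mismatching overlap positions take the base with
#' the higher quality when qualities are supplied, read 1's base otherwise.
#'
#' @param read1,read2 character vectors of equal length (read 2 in raw,
#'   un-reverse-complemented orientation).
#' @param min_overlap minimum overlap in bases (default 10).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @param quality1,quality2 optional Phred quality strings matching the
#'   reads.
#' @return character vector of merged sequences, `NA` where rejected.
#' @export
join_pairs <- function(read1, read2, min_overlap = 10L,
                       max_mismatch_frac = 0.1,
                       quality1 = NULL, quality2 = NULL) {
  read1 <- as.character(read1)
  read2 <- as.character(read2)
  if (length(read1) != length(read2))
    stop_aptashape("read1 and read2 must have equal length")
  if (!length(read1)) return(character(0))
  if (any(!nzchar(read1)) || any(!nzchar(read2)))
    stop_aptashape("reads must be non-empty")
  r2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read2)))
  q1 <- quality1 %||% character(0)
  q2r <- if (is.null(quality2)) character(0) else reverse_strings(quality2)
  .join_pairs_cpp(read1, r2rc, q1, q2r,
                  as.integer(min_overlap), as.numeric(max_mismatch_frac))
}

reverse_strings <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Extract the variable region between constant flanks
#'
#' Locates `flank5` (leftmost match) and then `flank3` (first match after
#' the 5' flank), each allowing up to `max_flank_mismatch` substitutions,
#' and returns the enclosed region when its length falls inside
#' `length_range`. Reads failing any step yield `NA`.
#'
#' @param merged character vector of merged amplicon sequences.
#' @param flank5,flank3 constant flanking sequences.
#' @param max_flank_mismatch substitutions tolerated per flank (default 1).
#' @param length_range admissible region length, inclusive
#'   (default `c(30, 42)`).
#' @return character vector of variable regions, `NA` where rejected.
#' @export
extract_variable_region <- function(merged, flank5, flank3,
                                    max_flank_mismatch = 1L,
                                    length_range = c(30L, 42L)) {
  if (!nzchar(flank5) || !nzchar(flank3))
    stop_aptashape("flanks must be non-empty")
  merged <- as.character(merged)
  if (!length(merged)) return(character(0))
  subj <- Biostrings::DNAStringSet(merged)
  m5 <- Biostrings::vmatchPattern(flank5, subj,
                                  max.mismatch = max_flank_mismatch)
  m3 <- Biostrings::vmatchPattern(flank3, subj,
                                  max.mismatch = max_flank_mismatch)
  s5 <- Biostrings::startIndex(m5)
  s3 <- Biostrings::startIndex(m3)
  out <- rep(NA_character_, length(merged))
  f5len <- nchar(flank5)
  for (i in seq_along(merged)) {
    a <- s5[[i]]
    if (is.null(a)) next
    start5 <- min(a)
    b <- s3[[i]]
    b <- b[b >= start5 + f5len]
    if (!length(b)) next
    start3 <- min(b)
    region <- substr(merged[i], start5 + f5len, start3 - 1)
    if (nchar(region) >= length_range[1] && nchar(region) <= length_range[2])
      out[i] <- region
  }
  out
}

#' Dereplicate sequences into counts
#'
#' Exact-sequence counting; the total count equals the number of input
#' sequences. Returned sorted by decreasing count, ties lexicographic.
#'
#' @param regions character vector of sequences (`NA`s are dropped).
#' @return named integer vector of counts.
#' @export
dereplicate <- function(regions) {
  regions <- regions[!is.na(regions)]
  if (!length(regions)) return(stats::setNames(integer(0), character(0)))
  tab <- table(regions)
  counts <- as.integer(tab)
  seqs <- names(tab)
  ord <- order(-counts, seqs)
  stats::setNames(counts[ord], seqs[ord])
}

#' Apply the per-sample minimum observation filter
#'
#' A sequence's count is zeroed in every sample where it was observed
#' fewer than `min_count` times; rows left with no observations are
#' dropped. Per-sample totals are deliberately unchanged: the
#' normalization denominator is the total read number of the sample, not
#' the retained subset.
#'
#' @param counts a [count_matrix()].
#' @param min_count minimum per-sample count (default 4).
#' @return filtered [count_matrix()].
#' @export
filter_min_count <- function(counts, min_count = 4L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_count < 1) stop_aptashape("min_count must be >= 1")
  m <- counts$counts
  m[m < min_count] <- 0
  keep <- rowSums(m) > 0
  structure(list(counts = m[keep, , drop = FALSE], totals = counts$totals),
            class = "count_matrix")
}

#' Cluster near-identical sequences by edit distance
#'
#' Greedy abundance-ordered centroid clustering under the optimal string
#' alignment distance ([damerau_levenshtein()]): sequences are visited in
#' order of decreasing total count (ties lexicographic); each joins the
#' first existing centroid within `max_dist`, otherwise founds a new one.
#' Member counts are summed into their centroid per sample. With
#' `max_dist = 3` this merges sequences at distance < 4, collapsing reads
#' stemming from single-nucleotide amplification or sequencing
#' differences onto their presumed ancestor.
#'
#' @param counts a [count_matrix()].
#' @param max_dist maximum distance to a centroid (default 3).
#' @return a [count_matrix()] of centroids with a `members` attribute
#'   (`data.frame` of member sequence and centroid).
#' @export
cluster_by_edit_distance <- function(counts, max_dist = 3L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (max_dist < 0) stop_aptashape("max_dist must be >= 0")
  m <- counts$counts
  if (nrow(m) == 0) return(counts)
  ord <- order(-rowSums(m), rownames(m))
  seqs <- rownames(m)[ord]
  cent_idx <- .greedy_cluster_cpp(seqs, as.integer(max_dist))
  centroid <- seqs[cent_idx]
  merged <- rowsum(m[ord, , drop = FALSE], group = centroid, reorder = FALSE)
  out <- structure(list(counts = merged, totals = counts$totals),
                   class = "count_matrix")
  attr(out, "members") <- data.frame(sequence = seqs, centroid = centroid,
                                     stringsAsFactors = FALSE)
  out
}

#' Convert counts to percent-of-pool frequencies
#'
#' Divides each sample's counts by that sample's total processed reads and
#' scales to percent, making abundances comparable across samples of
#' different sequencing depth.
#'
#' @param counts a [count_matrix()].
#' @return numeric matrix of percent-of-pool values.
#' @export
normalize_frequencies <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  zero <- names(counts$totals)[counts$totals <= 0]
  if (length(zero))
    stop_aptashape("zero total reads for sample(s): %s",
                   paste(zero, collapse = ", "))
  sweep(counts$counts, 2, counts$totals, "/") * 100
}

#' Keep the most abundant aptamers
#'
#' Ranks aptamers by mean frequency across all samples (ties broken
#' lexicographically by sequence) and keeps the top `n`, bounding the
#' multiple-testing burden of the downstream regression.
#'
#' @param freqs frequency matrix from [normalize_frequencies()].
#' @param n number to keep (default 1000).
#' @return frequency matrix restricted to the selected aptamers, ordered
#'   by decreasing mean frequency.
#' @export
select_top_abundant <- function(freqs, n = 1000L) {
  if (n < 1) stop_aptashape("n must be >= 1")
  if (nrow(freqs) < n)
    warning(sprintf("only %d aptamers available; keeping all (n = %d requested)",
                    nrow(freqs), n))
  ord <- order(-rowMeans(freqs), rownames(freqs))
  freqs[ord[seq_len(min(n, nrow(freqs)))], , drop = FALSE]
}

#' Process multiplexed FASTQ pairs into an aptamer count matrix
#'
#' Runs demultiplexing, pair-mate joining, variable-region extraction and
#' dereplication for every sample in the sheet. Identical read pairs are
#' collapsed before joining (their merge result is identical), which makes
#' deep noise-free data cheap to process. Per-sample totals are the
#' numbers of successfully extracted reads before any count filter.
#'
#' @param fastq1,fastq2 paths to the multiplexed mate files.
#' @param sheet a [sample_sheet()].
#' @param cfg a [pipeline_config()] (tolerances, flanks, length range).
#' @return a [count_matrix()] with a `stats` attribute summarising reads
#'   assigned, merged and extracted per sample.
#' @export
fastq_to_counts <- function(fastq1, fastq2, sheet, cfg = pipeline_config()) {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  if (length(r1) != length(r2))
    stop_aptashape("mate files differ in read count (%d vs %d)",
                   length(r1), length(r2))
  dm <- demultiplex(r1, sheet, cfg$max_barcode_mismatch)
  per_sample <- list()
  stats <- list()
  for (s in sheet$sample_id) {
    sel <- which(!is.na(dm$assignment) & dm$assignment == s)
    if (!length(sel)) {
      per_sample[[s]] <- stats::setNames(integer(0), character(0))
      stats[[s]] <- c(reads = 0L, merged = 0L, extracted = 0L)
      next
    }
    pair_key <- paste(r1[sel], r2[sel], sep = "|")
    tab <- table(pair_key)
    uniq <- names(tab)
    w <- as.integer(tab)
    parts <- strsplit(uniq, "|", fixed = TRUE)
    u1 <- vapply(parts, `[`, character(1), 1)
    u2 <- vapply(parts, `[`, character(1), 2)
    merged <- join_pairs(u1, u2, cfg$min_overlap, cfg$max_mismatch_frac)
    region <- rep(NA_character_, length(merged))
    ok <- !is.na(merged)
    if (any(ok))
      region[ok] <- extract_variable_region(
        merged[ok], cfg$flank5, cfg$flank3,
        cfg$max_flank_mismatch, cfg$length_range)
    keep <- !is.na(region)
    cnt <- if (any(keep)) {
      v <- rowsum(w[keep], group = region[keep], reorder = FALSE)
      stats::setNames(as.integer(v), rownames(v))
    } else stats::setNames(integer(0), character(0))
    ord <- order(-cnt, names(cnt))
    per_sample[[s]] <- cnt[ord]
    stats[[s]] <- c(reads = length(sel),
                    merged = sum(w[ok]),
                    extracted = sum(w[keep]))
  }
  all_seqs <- sort(unique(unlist(lapply(per_sample, names), use.names = FALSE)))
  m <- matrix(0, length(all_seqs), nrow(sheet),
              dimnames = list(all_seqs, sheet$sample_id))
  for (s in sheet$sample_id)
    m[names(per_sample[[s]]), s] <- per_sample[[s]]
  totals <- vapply(stats, function(x) as.numeric(x[["extracted"]]), numeric(1))
  # samples with nothing extracted keep total 0; normalization will flag them
  out <- count_matrix(m, pmax(totals, colSums(m)))
  attr(out, "stats") <- do.call(rbind, stats)
  attr(out, "demux") <- dm$stats
  out
}
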