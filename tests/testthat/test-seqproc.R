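two_sample_sheet <- function() {
  sample_sheet(c("s1", "s2"), c("AAGG", "CCTT"), c("C", "Ta"))
}

test_that("demultiplexing assigns by barcode prefix with mismatch budget", {
  sheet <- two_sample_sheet()
  exact <- demultiplex(c("AAGGACGT", "CCTTACGT", "AATGACGT"), sheet, 0)
  expect_equal(as.character(exact$assignment), c("s1", "s2", NA))
  expect_equal(unname(exact$stats["unassigned"]), 1L)
  # AATG is at Hamming distance 1 from AAGG and 4 from CCTT
  tol <- demultiplex("AATGACGT", sheet, max_mismatch = 1)
  expect_equal(as.character(tol$assignment), "s1")
})

test_that("barcode sets too close for the mismatch budget are rejected", {
  sheet <- sample_sheet(c("s1", "s2"), c("AAGG", "AAGT"), c("C", "Ta"))
  expect_error(demultiplex("AAGGACGT", sheet, max_mismatch = 1),
               "ambiguity")
})

test_that("pair joining reconstructs the fragment at the best offset", {
  # fragment ACGTACGTTT: read2 is the revcomp of its last 8 bases
  expect_equal(join_pairs("ACGTACGT", "AAACGTAC", min_overlap = 6),
               "ACGTACGTTT")
  # full-length revcomp mate: merged equals read1
  r1 <- "ACGGTTCA"
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r1)))
  expect_equal(join_pairs(r1, r2, min_overlap = 6), r1)
  # overlap below the minimum -> reject, not fatal
  expect_true(is.na(join_pairs("ACGTACGT", "AAACGTAC", min_overlap = 7)))
  # mismatch fraction above the cap -> reject
  expect_true(is.na(join_pairs("AAAAAAAA", "TTTTCCCC", min_overlap = 8,
                               max_mismatch_frac = 0.1)))
})

test_that("overlap conflicts resolve toward the higher-quality base", {
  # reads disagree at one overlap position; identical length, offset 0
  r1 <- "AAAAAAAA"
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("AAACAAAA")))
  # equal qualities: read1 wins
  expect_equal(join_pairs(r1, r2, min_overlap = 8, max_mismatch_frac = 0.2,
                          quality1 = strrep("F", 8),
                          quality2 = strrep("F", 8)), r1)
  # read2 higher quality at every base: its C survives
  expect_equal(join_pairs(r1, r2, min_overlap = 8, max_mismatch_frac = 0.2,
                          quality1 = strrep("#", 8),
                          quality2 = strrep("F", 8)), "AAACAAAA")
})

test_that("variable regions are extracted between approximate flanks", {
  f5 <- "GGGGCCACCAACGACATT"
  f3 <- "GTTGATATAAATAGTGCCCATGGATC"
  region36 <- strrep("ACGT", 9)
  expect_equal(extract_variable_region(paste0("NN", f5, region36, f3),
                                       f5, f3), region36)
  # one substitution in the 5' flank is tolerated, two are not
  f5_1mm <- sub("^G", "T", f5)
  f5_2mm <- sub("^GG", "TT", f5)
  expect_equal(extract_variable_region(paste0(f5_1mm, region36, f3), f5, f3),
               region36)
  expect_true(is.na(extract_variable_region(paste0(f5_2mm, region36, f3),
                                            f5, f3, max_flank_mismatch = 1)))
  # 29-nt region falls below the admissible length range
  expect_true(is.na(extract_variable_region(
    paste0(f5, strrep("A", 29), f3), f5, f3)))
})

test_that("dereplication counts exactly and conserves the total", {
  expect_equal(dereplicate(c("AC", "AC", "GT")), c(AC = 2L, GT = 1L))
  expect_equal(length(dereplicate(character(0))), 0L)
  withr::with_seed(1, {
    x <- sample(c("AA", "AC", "CA", "CC"), 57, replace = TRUE)
    expect_equal(sum(dereplicate(x)), length(x))
  })
})

test_that("min-count filter drops rare observations but keeps totals", {
  cm <- count_matrix(matrix(c(4L, 3L), 2, 1,
                            dimnames = list(c("AAAA", "CCCC"), "s1")))
  f <- filter_min_count(cm, 4)
  expect_equal(rownames(f$counts), "AAAA")
  expect_equal(unname(f$totals), 7)
  expect_equal(filter_min_count(cm, 1)$counts, cm$counts)
  none <- filter_min_count(cm, 10)
  expect_equal(nrow(none$counts), 0)
  expect_equal(unname(none$totals), 7)
})

test_that("greedy clustering merges by abundance-ordered centroids", {
  cm <- count_matrix(matrix(c(10L, 2L, 5L), 3, 1,
                            dimnames = list(c("AAAA", "AAAT", "CCCC"), "s1")))
  cl <- cluster_by_edit_distance(cm, 3)
  expect_equal(cl$counts[, 1], c(AAAA = 12, CCCC = 5))
  # max_dist 0: nothing merges
  cl0 <- cluster_by_edit_distance(cm, 0)
  expect_equal(nrow(cl0$counts), 3)
  # centroid (not single) linkage: C joins nothing because its distance to
  # the centroid A is 6 even though it is 3 away from member B
  a <- strrep("A", 12)
  b <- paste0(strrep("C", 3), strrep("A", 9))
  cc <- paste0(strrep("C", 3), strrep("G", 3), strrep("A", 6))
  cm2 <- count_matrix(matrix(c(10L, 5L, 4L), 3, 1,
                             dimnames = list(c(a, b, cc), "s1")))
  cl2 <- cluster_by_edit_distance(cm2, 3)
  expect_equal(cl2$counts[, 1], stats::setNames(c(15, 4), c(a, cc)))
})

test_that("clustering conserves per-sample counts", {
  withr::with_seed(7, {
    seqs <- unique(random_dna_vec(60, 8))
    m <- matrix(rpois(length(seqs) * 3, 5), ncol = 3,
                dimnames = list(seqs, c("s1", "s2", "s3")))
    cm <- count_matrix(m)
    cl <- cluster_by_edit_distance(cm, 2)
    expect_equal(colSums(cl$counts), colSums(m))
    # members partition the input
    expect_setequal(attr(cl, "members")$sequence, seqs)
  })
})

test_that("normalization yields percent of pool and inverts cleanly", {
  cm <- count_matrix(matrix(c(2L, 3L, 5L), 3, 1,
                            dimnames = list(c("AA", "CC", "GG"), "s1")),
                     totals = c(s1 = 10))
  expect_equal(unname(normalize_frequencies(cm)[, 1]), c(20, 30, 50))
  one <- count_matrix(matrix(6L, 1, 1, dimnames = list("AA", "s1")))
  expect_equal(unname(normalize_frequencies(one)[1, 1]), 100)
  zero <- structure(list(counts = matrix(0L, 1, 1,
                                         dimnames = list("AA", "bad")),
                         totals = c(bad = 0)), class = "count_matrix")
  expect_error(normalize_frequencies(zero), "bad")
  # round trip back to counts
  f <- normalize_frequencies(cm)
  expect_equal(sweep(f, 2, cm$totals, "*") / 100, cm$counts)
})

test_that("top-abundance selection ranks by mean with lexicographic ties", {
  f <- matrix(c(1, 5, 3,
                3, 5, 1), ncol = 2,
              dimnames = list(c("TT", "CC", "GG"), c("s1", "s2")))
  top2 <- select_top_abundant(f, 2)
  # CC leads on mean 5; GG and TT tie at mean 2, GG kept as the
  # lexicographically smaller sequence
  expect_equal(rownames(top2), c("CC", "GG"))
  expect_warning(select_top_abundant(f, 10), "keeping all")
  expect_equal(nrow(suppressWarnings(select_top_abundant(f, 10))), 3)
})
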