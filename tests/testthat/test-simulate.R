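test_that("pool generation produces normalized fractions and families", {
  cfg <- simulation_config(n_families = 0L, n_singletons = 5L, seed = 2)
  truth <- generate_pool(cfg)
  expect_equal(nrow(truth), 5)
  expect_equal(sum(truth$baseline), 1)
  expect_true(all(is.na(truth$family)))
  # zero mutation rate: family members identical to their ancestor (so the
  # redraw-on-duplicate guard must not fire here: check via rate > 0 family)
  cfg2 <- simulation_config(n_families = 3L, members_per_family = 4L,
                            n_singletons = 0L,
                            mutation_rate_within_family = 0.25, seed = 2)
  truth2 <- generate_pool(cfg2)
  expect_equal(as.integer(table(truth2$family)), rep(4L, 3))
  expect_equal(anyDuplicated(truth2$sequence), 0L)
  # oversized pool is impossible
  cfg3 <- simulation_config(n_families = 0L, n_singletons = 20L,
                            variable_region_length = 2L)
  expect_error(generate_pool(cfg3), "exceeds")
})

test_that("default pool shape matches the branched-selection pool", {
  # top aptamer around a tenth of the pool; the vast majority individually
  # below one percent
  tops <- numeric(20)
  under1 <- numeric(20)
  for (s in 1:20) {
    truth <- generate_pool(simulation_config(seed = s))
    tops[s] <- max(truth$baseline)
    under1[s] <- mean(truth$baseline < 0.01)
  }
  expect_gt(mean(tops), 0.05)
  expect_lt(mean(tops), 0.2)
  expect_true(all(under1 > 0.9))
})

test_that("branched counts conserve depth and respect multipliers", {
  cfg <- simulation_config(n_families = 0L, n_singletons = 50L,
                           sample_noise_sigma = 0,
                           read_depth = 100000L,
                           n_per_group = c(C = 32L, Ta = 32L, T2T4 = 32L),
                           seed = 5)
  truth <- generate_pool(cfg)
  i <- which.min(abs(truth$baseline - stats::median(truth$baseline)))
  truth <- plant_effects(truth, data.frame(index = i,
                                           comparison = "Ta_vs_T2T4",
                                           multiplier = 2))
  sheet <- sim_sample_sheet(cfg)
  sim <- simulate_branched_counts(truth, sheet, cfg)
  # multinomial conservation
  expect_true(all(colSums(sim$counts$counts) == cfg$read_depth))
  expect_equal(unname(sim$counts$totals), rep(1e5, 96))
  # noise-free expected frequency equals renormalized baseline x multiplier
  w <- truth$baseline * truth$mult_C
  expect_equal(unname(sim$expected_freq[, 1]), 100 * w / sum(w))
  # empirical frequency ratio T2T4/C within 3 SE of the expectation ratio
  fr <- normalize_frequencies(sim$counts)
  grp <- as.character(sheet$group)
  f_t <- fr[i, grp == "T2T4"] / 100
  f_c <- fr[i, grp == "C"] / 100
  wT <- truth$baseline * truth$mult_T2T4
  expected_ratio <- (wT[i] / sum(wT)) / (w[i] / sum(w))
  se_ratio <- expected_ratio *
    sqrt(var(f_t) / (32 * mean(f_t)^2) + var(f_c) / (32 * mean(f_c)^2))
  expect_lt(abs(mean(f_t) / mean(f_c) - expected_ratio), 3 * se_ratio)
})

test_that("planted effects multiply whole families and are validated", {
  cfg <- simulation_config(n_families = 2L, members_per_family = 3L,
                           n_singletons = 4L, seed = 9)
  truth <- generate_pool(cfg)
  planted <- plant_effects(truth, data.frame(index = 1, # member of family 1
                                             comparison = "vsC_cancer",
                                             multiplier = 0.5))
  fam1 <- planted$family == "F001" & !is.na(planted$family)
  expect_true(all(planted$mult_Ta[fam1] == 0.5))
  expect_true(all(planted$mult_T2T4[fam1] == 0.5))
  expect_true(all(planted$mult_C == 1))
  expect_true(all(planted$planted[fam1]))
  expect_error(plant_effects(truth, data.frame(index = 1, comparison = "x",
                                               multiplier = 2)),
               "unknown comparison")
  expect_error(plant_effects(truth, data.frame(index = 1,
                                               comparison = "vsC_cancer",
                                               multiplier = 0)),
               "> 0")
})

test_that("emitted FASTQ pairs round-trip exactly through read processing", {
  cfg <- simulation_config(n_families = 4L, members_per_family = 2L,
                           n_singletons = 12L, read_depth = 1500L,
                           n_per_group = c(C = 2L, Ta = 2L, T2T4 = 2L),
                           sample_noise_sigma = 0, seed = 13)
  truth <- generate_pool(cfg)
  sheet <- sim_sample_sheet(cfg)
  sim <- simulate_branched_counts(truth, sheet, cfg)
  dir <- withr::local_tempdir()
  paths <- write_fastq_pairs(sim$counts, sheet, cfg, dir)
  rec <- fastq_to_counts(paths[["R1"]], paths[["R2"]], sheet,
                         pipeline_config())
  orig <- sim$counts$counts[rowSums(sim$counts$counts) > 0, , drop = FALSE]
  expect_equal(rec$counts[rownames(orig), colnames(orig)], orig)
  expect_equal(unname(rec$totals), unname(colSums(orig)))
  # reads partition exactly by barcode
  r1 <- Biostrings::readDNAStringSet(paths[["R1"]], format = "fastq")
  prefixes <- substr(as.character(r1), 1, cfg$barcode_length)
  expect_setequal(unique(prefixes), sheet$barcode)
  expect_equal(unname(table(prefixes)[sheet$barcode]),
               unname(colSums(orig)), ignore_attr = TRUE)
})

test_that("FASTQ emission handles edge cases", {
  cfg <- simulation_config(seed = 1)
  sheet <- sample_sheet("s1", "AAGGCC", "C")
  empty <- count_matrix(matrix(integer(0), 0, 1,
                               dimnames = list(character(0), "s1")))
  dir <- withr::local_tempdir()
  paths <- write_fastq_pairs(empty, sheet, cfg, dir)
  expect_equal(length(readLines(paths[["R1"]])), 0)
  short <- cfg
  short$read_length <- 10L
  cm <- count_matrix(matrix(2L, 1, 1,
                            dimnames = list(strrep("ACGT", 9), "s1")))
  expect_error(write_fastq_pairs(cm, sheet, short, dir), "read_length")
})

test_that("two-cohort studies are reproducible functions of the seed", {
  cfg <- simulation_config(n_families = 5L, members_per_family = 2L,
                           n_singletons = 30L, read_depth = 5000L,
                           n_per_group = c(C = 4L, Ta = 4L, T2T4 = 4L),
                           seed = 21)
  a <- simulate_study(cfg, n_validation_per_group = c(C = 3L, Ta = 2L, T2T4 = 2L))
  b <- simulate_study(cfg, n_validation_per_group = c(C = 3L, Ta = 2L, T2T4 = 2L))
  expect_identical(a, b)
  expect_equal(sum(a$sheet$cohort == "validation"), 7)
  # validation counts differ from training counts (independent sampling)
  expect_false(identical(a$counts$counts[, "tr_C_01"],
                         a$counts$counts[, "va_C_01"]))
})
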