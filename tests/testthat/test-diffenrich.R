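test_that("relative levels rescale rows to mean 1", {
  f <- matrix(c(1, 2, 3,
                4, 4, 4,
                0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("AA", "CC", "GG"), c("s1", "s2", "s3")))
  expect_warning(lv <- relative_to_mean(f), "zero mean")
  expect_equal(unname(lv["AA", ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(lv["CC", ]), c(1, 1, 1))
  expect_false("GG" %in% rownames(lv))
  expect_true(all(abs(rowMeans(lv) - 1) < 1e-12))
})

two_group_sheet <- function(n_c, n_ta) {
  sample_sheet(sprintf("s%02d", seq_len(n_c + n_ta)),
               enumerate_dna(n_c + n_ta),
               rep(c("C", "Ta"), c(n_c, n_ta)))
}

enumerate_dna <- function(n) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(bases, bases, bases, stringsAsFactors = FALSE)
  do.call(paste0, grid)[seq_len(n)]
}

test_that("group OLS reproduces the closed-form pooled two-sample test", {
  sheet <- two_group_sheet(2, 2)
  lv <- matrix(c(1, 2, 2, 3), 1, 4,
               dimnames = list("AAAA", sheet$sample_id))
  res <- fit_group_ols(lv, sheet, baseline = "C")
  expect_equal(res$comparison, "Ta_vs_C")
  expect_equal(res$beta, 1.0)
  expect_equal(res$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(res$t, sqrt(2), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-sqrt(2), 2), tolerance = 1e-12)
  # identical group means -> beta 0
  lv0 <- matrix(c(1, 3, 2, 2), 1, 4,
                dimnames = list("AAAA", sheet$sample_id))
  expect_equal(fit_group_ols(lv0, sheet)$beta, 0)
})

test_that("group OLS matches the pooled-t oracle on random instances", {
  withr::with_seed(101, {
    for (rep in 1:250) {
      n_c <- sample(2:6, 1)
      n_ta <- sample(2:6, 1)
      sheet <- two_group_sheet(n_c, n_ta)
      y <- rnorm(n_c + n_ta)
      lv <- matrix(y, 1, dimnames = list("AAAA", sheet$sample_id))
      res <- fit_group_ols(lv, sheet, baseline = "C")
      want <- pooled_t_oracle(y[seq_len(n_c)], y[-seq_len(n_c)])
      expect_equal(res$beta, want$beta, tolerance = 1e-10)
      expect_equal(res$se, want$se, tolerance = 1e-10)
      expect_equal(res$t, want$t, tolerance = 1e-10)
      expect_equal(res$p, want$p, tolerance = 1e-10)
    }
  })
})

test_that("three-group OLS agrees with lm() dummy coding", {
  withr::with_seed(7, {
    sheet <- sample_sheet(sprintf("s%02d", 1:12), enumerate_dna(12),
                          rep(c("C", "Ta", "T2T4"), each = 4))
    lv <- matrix(rnorm(36), 3, 12,
                 dimnames = list(c("AAAA", "CCCC", "GGGG"), sheet$sample_id))
    res <- fit_group_ols(lv, sheet, baseline = "C")
    fac <- factor(as.character(sheet$group), levels = c("C", "Ta", "T2T4"))
    for (a in rownames(lv)) {
      fit <- lm(lv[a, ] ~ fac)
      cf <- summary(fit)$coefficients
      for (g in c("Ta", "T2T4")) {
        row <- res[res$sequence == a &
                     res$comparison == paste0(g, "_vs_C"), ]
        want <- cf[paste0("fac", g), ]
        expect_equal(row$beta, unname(want["Estimate"]), tolerance = 1e-10)
        expect_equal(row$se, unname(want["Std. Error"]), tolerance = 1e-10)
        expect_equal(row$p, unname(want["Pr(>|t|)"]), tolerance = 1e-10)
      }
    }
    # beta always equals group mean minus baseline mean
    grp <- as.character(sheet$group)
    expect_equal(res$beta[res$comparison == "Ta_vs_C"],
                 unname(rowMeans(lv[, grp == "Ta"]) -
                          rowMeans(lv[, grp == "C"])))
  })
})

test_that("degenerate and undersized fits are flagged", {
  sheet <- two_group_sheet(2, 2)
  lv <- matrix(c(1, 1, 2, 2), 1, 4,
               dimnames = list("AAAA", sheet$sample_id))
  res <- fit_group_ols(lv, sheet)
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
  small <- sample_sheet(c("a", "b", "c"), enumerate_dna(3),
                        c("C", "C", "Ta"))
  lv2 <- matrix(1:3, 1, 3, dimnames = list("AAAA", small$sample_id))
  expect_error(fit_group_ols(lv2, small), "fewer than 2")
})

test_that("Benjamini-Hochberg adjustment matches hand-computed step-up", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(c(0.5, 0.005)), c(0.5, 0.01))  # order preserved
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(3, {
    p <- runif(50)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone on sorted p
  })
})

test_that("discriminatory selection applies per-comparison thresholds", {
  results <- data.frame(
    sequence = strrep(c("A", "C", "G", "T", "AC"), 4),
    comparison = c("T2T4_vs_C", "T2T4_vs_C", "T2T4_vs_Ta", "T2T4_vs_Ta",
                   "Ta_vs_C"),
    beta = c(-0.6, -0.4, 0.3, 0.2, 0.55),
    se = 0.1, t = 1, df = 10, p = 0.001, degenerate = FALSE,
    adj_p = c(0.005, 0.001, 0.005, 0.005, 0.02)
  )
  sel <- select_discriminatory(results, pipeline_config())
  # -0.6 passes 0.5 gate; -0.4 does not; 0.3 passes the 0.25 stage gate;
  # 0.2 does not; 0.55 fails the p gate
  expect_equal(sel$sequence, c("AAAA", "GGGG"))
  expect_equal(sel$comparison, c("T2T4_vs_C", "T2T4_vs_Ta"))
  expect_equal(sel$direction, c("depleted", "increased"))
})

test_that("family grouping is single linkage on edit distance", {
  a <- strrep("A", 24)
  b <- paste0(strrep("C", 8), strrep("A", 16))                 # d(a,b) = 8
  c_ <- paste0(strrep("C", 8), strrep("G", 8), strrep("A", 8)) # d(b,c) = 8
  expect_equal(damerau_levenshtein(a, c_), 16L)
  fam <- group_into_families(c(a, b, c_), family_max_dist = 8)
  expect_equal(unname(fam), c("A", "A", "A"))  # chained into one family
  far <- c(strrep("A", 24), strrep("C", 24), strrep("G", 24))
  expect_true(all(is.na(group_into_families(far, 8))))
  same <- group_into_families(c(a, a, b), 8)
  expect_equal(unname(same[1]), unname(same[2]))
})

test_that("selection is invariant to row and column permutations", {
  study <- moderate_study(seed = 31L, depth = 20000L)
  counts <- study$counts
  base <- run_diffenrich(counts, study$sheet)
  perm_rows <- sample(nrow(counts$counts))
  perm_cols <- sample(ncol(counts$counts))
  shuffled <- count_matrix(counts$counts[perm_rows, perm_cols],
                           counts$totals[perm_cols])
  again <- run_diffenrich(shuffled, study$sheet)
  expect_equal(base$disc[order(base$disc$sequence, base$disc$comparison), ],
               again$disc[order(again$disc$sequence, again$disc$comparison), ],
               ignore_attr = TRUE)
})
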