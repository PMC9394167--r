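#' Rescale frequencies to relative levels
#'
#' Divides every aptamer's frequencies by its mean across all samples, so
#' that each aptamer varies around 1 and the degree of variation is
#' comparable between abundant and rare aptamers. This is the response
#' variable of the group regression.
#'
#' @param freqs frequency matrix (aptamers x samples).
#' @return matrix of relative levels; rows with zero mean are dropped with
#'   a warning (they cannot be rescaled).
#' @export
relative_to_mean <- function(freqs) {
  mu <- rowMeans(freqs)
  drop <- mu <= 0
  if (any(drop)) {
    warning(sprintf("dropping %d aptamer(s) with zero mean frequency: %s",
                    sum(drop),
                    paste(head(rownames(freqs)[drop], 5), collapse = ", ")))
    freqs <- freqs[!drop, , drop = FALSE]
    mu <- mu[!drop]
  }
  freqs / mu
}

comparison_levels <- c("Ta_vs_C", "T2T4_vs_C", "T2T4_vs_Ta")

#' Per-aptamer group regression (OLS with indicator coding)
#'
#' Fits, for every aptamer, the unweighted linear model
#' `level ~ group` with indicator coding relative to `baseline` over all
#' samples of the sheet present in the matrix. With indicator coding the
#' coefficient of group `g` equals the difference between that group's
#' mean and the baseline mean; its standard error uses the pooled residual
#' variance with `n - k` degrees of freedom (`k` = number of groups), and
#' the two-sided p-value comes from the corresponding Student's
#' t-distribution. Closed-form least squares is used for speed; it is
#' algebraically identical to `lm(level ~ group)`.
#'
#' @param levels relative-level matrix (aptamers x samples).
#' @param sheet a [sample_sheet()]; only its samples present as columns
#'   are used.
#' @param baseline reference group (`"C"`, `"Ta"` or `"T2T4"`).
#' @return `data.frame` with one row per aptamer and non-baseline group:
#'   `sequence`, `comparison` (`"<group>_vs_<baseline>"`), `beta`, `se`,
#'   `t`, `df`, `p`, `degenerate` (zero residual variance).
#' @export
fit_group_ols <- function(levels, sheet, baseline = "C") {
  stopifnot(inherits(sheet, "aptashape_sheet"))
  baseline <- match.arg(baseline, group_levels)
  samples <- intersect(colnames(levels), sheet$sample_id)
  if (!length(samples)) stop_aptashape("no sheet samples found in matrix")
  grp <- as.character(sheet$group[match(samples, sheet$sample_id)])
  groups <- intersect(group_levels, unique(grp))
  if (!(baseline %in% groups))
    stop_aptashape("baseline group %s has no samples", baseline)
  ng <- table(factor(grp, levels = groups))
  if (any(ng < 2))
    stop_aptashape("group(s) with fewer than 2 samples: %s",
                   paste(names(ng)[ng < 2], collapse = ", "))
  y <- levels[, samples, drop = FALSE]
  n <- length(samples)
  k <- length(groups)
  gsum <- t(rowsum(t(y), group = grp))  # aptamers x groups (sorted names)
  gsum <- gsum[, groups, drop = FALSE]
  gmeans <- sweep(gsum, 2, as.numeric(ng), "/")
  rss <- rowSums(y^2) - as.numeric(gmeans^2 %*% as.numeric(ng))
  rss <- pmax(rss, 0)  # guard tiny negative rounding
  dfres <- n - k
  s2 <- rss / dfres
  others <- setdiff(groups, baseline)
  out <- do.call(rbind, lapply(others, function(g) {
    beta <- gmeans[, g] - gmeans[, baseline]
    se <- sqrt(s2 * (1 / ng[[g]] + 1 / ng[[baseline]]))
    degenerate <- s2 <= 0
    tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
    p <- ifelse(degenerate & beta != 0, 0, 2 * pt(-abs(tstat), dfres))
    data.frame(sequence = rownames(y),
               comparison = paste0(g, "_vs_", baseline),
               beta = unname(beta), se = unname(se), t = unname(tstat),
               df = dfres, p = unname(p), degenerate = unname(degenerate),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: after sorting ascending,
#' `adj_(i) = min_{j >= i} (m/j) p_(j)` capped at 1, returned in the
#' original order (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_aptashape("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Full three-comparison differential-enrichment test
#'
#' Runs the group regression twice — once with the control group as
#' baseline (yielding Ta vs C and T2T4 vs C) and once with the Ta group as
#' baseline (yielding T2T4 vs Ta) — and adjusts p-values per comparison
#' across the tested aptamers with [bh_adjust()].
#'
#' @param levels relative-level matrix.
#' @param sheet a [sample_sheet()].
#' @return `data.frame` (the OLS result table) with columns of
#'   [fit_group_ols()] plus `adj_p`.
#' @export
test_differential_enrichment <- function(levels, sheet) {
  res_c <- fit_group_ols(levels, sheet, baseline = "C")
  res_ta <- fit_group_ols(levels, sheet, baseline = "Ta")
  res <- rbind(res_c, res_ta[res_ta$comparison == "T2T4_vs_Ta", ])
  res <- res[res$comparison %in% comparison_levels, ]
  res$adj_p <- NA_real_
  for (cmp in unique(res$comparison)) {
    i <- res$comparison == cmp
    res$adj_p[i] <- bh_adjust(res$p[i])
  }
  res <- res[order(match(res$comparison, comparison_levels), res$sequence), ]
  rownames(res) <- NULL
  res
}

#' Select discriminatory aptamers
#'
#' An aptamer is discriminatory for a vs-control comparison when
#' `|beta| > coef_threshold_vs_C` with adjusted p below
#' `adj_p_threshold`, and for the stage comparison (T2T4 vs Ta) when
#' `|beta| > coef_threshold_Ta_vs_T2T4` with the same p gate. The sign of
#' the coefficient gives the direction: depleted (negative) or increased
#' (positive) relative to the baseline group. Selected aptamers are
#' grouped into sequence families with [group_into_families()].
#'
#' @param results OLS result table from [test_differential_enrichment()].
#' @param cfg a [pipeline_config()].
#' @return `data.frame` with one row per (aptamer, triggering comparison):
#'   `sequence`, `comparison`, `beta`, `adj_p`, `direction`, `family`.
#' @export
select_discriminatory <- function(results, cfg = pipeline_config()) {
  thr <- ifelse(results$comparison == "T2T4_vs_Ta",
                cfg$coef_threshold_Ta_vs_T2T4, cfg$coef_threshold_vs_C)
  hit <- abs(results$beta) > thr & results$adj_p < cfg$adj_p_threshold
  sel <- results[hit, c("sequence", "comparison", "beta", "adj_p")]
  sel$direction <- ifelse(sel$beta < 0, "depleted", "increased")
  fam <- group_into_families(unique(sel$sequence), cfg$family_max_dist)
  sel$family <- unname(fam[sel$sequence])
  sel <- sel[order(match(sel$comparison, comparison_levels), sel$sequence), ]
  rownames(sel) <- NULL
  class(sel) <- c("discriminatory_set", "data.frame")
  sel
}

#' Group sequences into families by single-linkage edit distance
#'
#' Surrogate for motif-level family assignment: two sequences belong to
#' the same family when connected by a chain of pairwise optimal string
#' alignment distances at most `family_max_dist` (single linkage, i.e.
#' connected components of the threshold graph). Families of at least two
#' members are labelled `A`, `B`, ... in order of decreasing size (ties
#' broken by the lexicographically smallest member); singletons get `NA`.
#'
#' @param seqs character vector of sequences.
#' @param family_max_dist distance threshold (default 8).
#' @return named character vector of family labels (names = sequences).
#' @export
group_into_families <- function(seqs, family_max_dist = 8L) {
  seqs <- unique(as.character(seqs))
  n <- length(seqs)
  labels <- stats::setNames(rep(NA_character_, n), seqs)
  if (n == 0) return(labels)
  d <- .osa_distmat_cpp(seqs, as.integer(family_max_dist))
  adj <- d <= family_max_dist
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  fams <- which(sizes >= 2)
  if (length(fams)) {
    first_member <- vapply(fams, function(f) min(seqs[comp == f]), character(1))
    fams <- fams[order(-sizes[fams], first_member)]
    for (j in seq_along(fams))
      labels[comp == fams[j]] <- family_label(j)
  }
  labels
}

# A..Z, then AA, AB, ...
family_label <- function(j) {
  if (j <= 26) return(LETTERS[j])
  paste0(LETTERS[(j - 1) %/% 26], LETTERS[(j - 1) %% 26 + 1])
}
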