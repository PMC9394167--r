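#' Hierarchically cluster sample columns
#'
#' Agglomerative clustering of the sample columns of a relative-level
#' matrix (complete linkage on Euclidean distances by default), as used to
#' order heatmap columns; rows are left in their family order and are not
#' clustered. The tree is also serialised to Newick for export.
#'
#' @param levels matrix (aptamers x samples) restricted to the
#'   discriminatory aptamers.
#' @param method linkage (default `"complete"`).
#' @param metric distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @return list with `order` (sample ids in dendrogram order), `hclust`
#'   (the tree, `NULL` for a single column) and `newick`.
#' @export
hierarchical_cluster_columns <- function(levels, method = "complete",
                                         metric = "euclidean") {
  samples <- colnames(levels)
  if (length(samples) < 1) stop_aptashape("no sample columns to cluster")
  if (length(samples) == 1) {
    return(list(order = samples, hclust = NULL,
                newick = paste0("(", samples, ");")))
  }
  hc <- hclust(dist(t(levels), method = metric), method = method)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(order = samples[hc$order], hclust = hc, newick = nwk)
}

#' Principal component analysis of sample profiles
#'
#' Thin wrapper around [stats::prcomp()] on a samples-by-aptamers matrix:
#' columns are mean-centered (default) and optionally unit-scaled; the
#' component variance fractions are the covariance eigenvalues divided by
#' their sum.
#'
#' @param x numeric matrix, samples as rows, aptamers as columns.
#' @param center,scale. passed to [stats::prcomp()] (defaults: center on,
#'   scale off).
#' @return object of class `aptashape_pca`: list with `scores`
#'   (samples x components), `loadings` (aptamers x components),
#'   `var_frac`, `sdev`.
#' @export
pca_fit <- function(x, center = TRUE, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 1)
    stop_aptashape("PCA needs at least 2 samples and 1 aptamer")
  p <- prcomp(x, center = center, scale. = scale.)
  if (all(p$sdev == 0)) stop_aptashape("matrix has zero variance")
  structure(list(
    scores = p$x,
    loadings = p$rotation,
    var_frac = p$sdev^2 / sum(p$sdev^2),
    sdev = p$sdev
  ), class = "aptashape_pca")
}

#' @export
print.aptashape_pca <- function(x, ...) {
  cat(sprintf("<aptashape_pca> %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  vf <- sprintf("PC%d=%.1f%%", seq_along(x$var_frac), 100 * x$var_frac)
  cat("variance:", paste(head(vf, 5), collapse = " "), "\n")
  invisible(x)
}

#' Orient principal components by group sign convention
#'
#' Principal-component signs are arbitrary; the sign rule used for
#' classification requires a fixed convention: cancer samples (Ta and
#' T2T4) positive on component 1, late-stage (T2T4) samples positive on
#' component 2. Components whose labeled-group mean score violates the
#' convention are flipped (scores and loadings together); flipping twice
#' is the identity.
#'
#' @param pca an `aptashape_pca`.
#' @param sheet a [sample_sheet()] with the true group of each scored
#'   sample.
#' @return the oriented `aptashape_pca`, with a `flipped` logical vector
#'   recording which components changed sign.
#' @export
orient_components <- function(pca, sheet) {
  stopifnot(inherits(pca, "aptashape_pca"), inherits(sheet, "aptashape_sheet"))
  grp <- sheet$group[match(rownames(pca$scores), sheet$sample_id)]
  k <- ncol(pca$scores)
  flipped <- rep(FALSE, k)
  if (all(is.na(grp))) {
    warning("no labeled samples; component orientation left unchanged")
  } else {
    cancer <- !is.na(grp) & grp %in% c("Ta", "T2T4")
    if (any(cancer) && mean(pca$scores[cancer, 1]) < 0) flipped[1] <- TRUE
    late <- !is.na(grp) & grp == "T2T4"
    if (k >= 2 && any(late) && mean(pca$scores[late, 2]) < 0) flipped[2] <- TRUE
  }
  if (any(flipped)) {
    pca$scores[, flipped] <- -pca$scores[, flipped, drop = FALSE]
    pca$loadings[, flipped] <- -pca$loadings[, flipped, drop = FALSE]
  }
  pca$flipped <- flipped
  pca
}

#' Classify samples from the signs of their component scores
#'
#' Implements the sign rule on an oriented PCA: a positive coordinate on
#' component 1 calls a sample cancer, non-positive calls it control (a
#' score of exactly 0 counts as control); among cancer samples, a positive
#' coordinate on component 2 calls late stage (T2T4), otherwise early
#' stage (Ta). Mode `"combined"` applies both rules to the same PCA.
#'
#' @param pca an oriented `aptashape_pca` (see [orient_components()]).
#' @param sheet a [sample_sheet()] providing the true groups.
#' @param mode `"cancer_vs_control"`, `"Ta_vs_T2T4"` or `"combined"`.
#' @return `data.frame` of class `classification_result`: `sample_id`,
#'   `task`, `score`, `predicted`, `truth`, `correct`; per-task accuracies
#'   in the `accuracy` attribute.
#' @export
classify_by_sign <- function(pca, sheet,
                             mode = c("cancer_vs_control", "Ta_vs_T2T4",
                                      "combined")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pca, "aptashape_pca"))
  grp <- sheet$group[match(rownames(pca$scores), sheet$sample_id)]
  if (anyNA(grp))
    stop_aptashape("sample(s) missing from sheet: %s",
                   paste(rownames(pca$scores)[is.na(grp)], collapse = ", "))
  res <- list()
  if (mode %in% c("cancer_vs_control", "combined")) {
    sc <- pca$scores[, 1]
    res$cancer_vs_control <- data.frame(
      sample_id = rownames(pca$scores),
      task = "cancer_vs_control",
      score = unname(sc),
      predicted = ifelse(sc > 0, "cancer", "control"),
      truth = ifelse(grp == "C", "control", "cancer"),
      stringsAsFactors = FALSE
    )
  }
  if (mode %in% c("Ta_vs_T2T4", "combined")) {
    cancer <- grp %in% c("Ta", "T2T4")
    if (!any(cancer))
      stop_aptashape("Ta_vs_T2T4 classification requires cancer samples")
    if (ncol(pca$scores) < 2)
      stop_aptashape("Ta_vs_T2T4 classification requires a second component")
    sc <- pca$scores[cancer, 2]
    res$Ta_vs_T2T4 <- data.frame(
      sample_id = rownames(pca$scores)[cancer],
      task = "Ta_vs_T2T4",
      score = unname(sc),
      predicted = ifelse(sc > 0, "T2T4", "Ta"),
      truth = as.character(grp[cancer]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$correct <- out$predicted == out$truth
  acc <- vapply(split(out, out$task),
                function(d) accuracy(d$predicted, d$truth), numeric(1))
  attr(out, "accuracy") <- acc
  class(out) <- c("classification_result", "data.frame")
  out
}

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors.
#' @return fraction of exact matches.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop_aptashape("pred and truth differ in length (%d vs %d)",
                   length(pred), length(truth))
  if (!length(pred)) stop_aptashape("empty label vectors")
  mean(pred == truth)
}
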