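#' Damerau-Levenshtein (optimal string alignment) edit distance
#'
#' Edit distance with unit-cost substitutions, insertions, deletions and
#' adjacent transpositions, in the restricted "optimal string alignment"
#' (OSA) variant in which no substring is edited more than once. This is the
#' variant implemented by most string-distance libraries under the name
#' Damerau-Levenshtein, and the one used here to merge aptamer reads that
#' stem from single-nucleotide sequencing or amplification differences.
#'
#' The restriction matters: for `("CA", "ABC")` OSA gives 3 whereas the
#' unrestricted Damerau-Levenshtein distance is 2.
#'
#' @param a,b character vectors of sequences; recycled to a common length
#'   when one has length 1.
#' @return integer vector of pairwise distances.
#' @examples
#' damerau_levenshtein("ACGT", "ACTG")  # one adjacent transposition -> 1
#' damerau_levenshtein("CA", "ABC")     # 3 under OSA
#' @export
damerau_levenshtein <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  .osa_distance_cpp(a, b)
}

# Full pairwise distance matrix; distances above `cap` are reported as
# cap + 1 (sufficient for thresholded clustering).
osa_distance_matrix <- function(seqs, cap = .Machine$integer.max %/% 2L) {
  d <- .osa_distmat_cpp(as.character(seqs), as.integer(cap))
  dimnames(d) <- list(seqs, seqs)
  d
}
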