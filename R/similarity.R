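#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return Numeric in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  u <- union(set_a, set_b)
  if (length(u) == 0) return(0)
  length(intersect(set_a, set_b)) / length(u)
}

#' Cross-cohort cluster similarity matrix
#'
#' Pairwise Jaccard similarity between every cluster's specific-gene set in
#' cohort A and every set in cohort B.
#'
#' @param sets_a,sets_b named lists of gene sets (e.g. from
#'   [specific_gene_sets()]).
#' @return Matrix (clusters A x clusters B) with the list names as dimnames.
#' @export
cross_cohort_matrix <- function(sets_a, sets_b) {
  if (!length(sets_a) || !length(sets_b)) {
    stop("cross_cohort_matrix: both cohorts need at least one cluster set")
  }
  m <- outer(seq_along(sets_a), seq_along(sets_b),
             Vectorize(function(i, j) jaccard(sets_a[[i]], sets_b[[j]])))
  dimnames(m) <- list(names(sets_a), names(sets_b))
  m
}

#' Strongest cross-cohort cluster pairs
#'
#' Top-k entries of a similarity matrix by value; ties broken by ascending
#' (row index, column index).
#'
#' @param matrix similarity matrix from [cross_cohort_matrix()].
#' @param k number of pairs (all pairs if `k` exceeds the matrix size).
#' @return data.frame `cluster_a`, `cluster_b`, `value`, strongest first.
#' @export
top_pairs <- function(matrix, k = 3) {
  idx <- which(!is.na(matrix), arr.ind = TRUE)
  d <- data.frame(
    cluster_a = if (!is.null(rownames(matrix))) rownames(matrix)[idx[, 1]]
                else as.character(idx[, 1]),
    cluster_b = if (!is.null(colnames(matrix))) colnames(matrix)[idx[, 2]]
                else as.character(idx[, 2]),
    value = matrix[idx],
    stringsAsFactors = FALSE
  )
  d <- d[order(-d$value, idx[, 1], idx[, 2]), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, k)
}
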