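#' Cluster marker genes by Wilcoxon rank-sum test
#'
#' For every cluster, each gene is tested in-cluster versus all other cells
#' with a two-sided Wilcoxon rank-sum test. Small, tie-free comparisons
#' (both groups of at most 8 cells) use the exact rank-sum distribution;
#' otherwise the normal approximation with tie correction is used. The fold
#' change is computed on de-logged means with a pseudocount of 1:
#' `log2FC = log2((mean(expm1 in) + 1) / (mean(expm1 out) + 1))`. P-values
#' are Benjamini-Hochberg adjusted across genes within each cluster, and a
#' gene is flagged `specific` when `p_adj < p_adj_cutoff` and
#' `|log2FC| > log2fc_cutoff` (and, if requested, expressed in at least
#' `min_pct` of the in-cluster cells).
#'
#' @param norm log-normalized genes x cells matrix.
#' @param labels cluster id per cell (integer or factor).
#' @param p_adj_cutoff adjusted-p threshold for the `specific` flag.
#' @param log2fc_cutoff absolute log2 fold-change threshold.
#' @param min_pct optional minimum in-cluster detection fraction (0 = off).
#' @param min_cells clusters with fewer cells are skipped with a warning
#'   (their cells still count as background for other clusters).
#' @return data.frame with columns `cluster`, `gene`, `log2fc`, `p`,
#'   `p_adj`, `specific`.
#' @export
rank_markers <- function(norm, labels, p_adj_cutoff = 0.05,
                         log2fc_cutoff = 1, min_pct = 0, min_cells = 3) {
  norm <- as.matrix(norm)
  if (is.factor(labels)) labels <- as.character(labels)
  labels <- as.integer(labels)
  n <- ncol(norm)
  stopifnot(length(labels) == n)
  clusters <- sort(unique(labels))
  sizes <- table(labels)
  small <- clusters[sizes[as.character(clusters)] < min_cells]
  if (length(small)) {
    warning("rank_markers: cluster(s) ",
            paste(small, collapse = ", "),
            " have fewer than ", min_cells, " cells and are skipped")
    clusters <- setdiff(clusters, small)
  }
  if (!length(clusters)) stop("rank_markers: no cluster large enough to test")

  expd <- expm1(norm)
  ranks <- t(apply(norm, 1, rank)) # ties get average ranks
  # tie term sum(t^3 - t) per gene; depends only on the pooled values
  tie_term <- apply(norm, 1, function(x) {
    tt <- tabulate(match(x, unique(x)))
    sum(tt^3 - tt)
  })
  genes <- rownames(norm)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(norm)))

  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    idx <- which(labels == cl)
    n1 <- length(idx); n2 <- n - n1
    mean_in <- rowMeans(expd[, idx, drop = FALSE])
    mean_out <- rowMeans(expd[, -idx, drop = FALSE])
    log2fc <- log2((mean_in + 1) / (mean_out + 1))

    if (max(n1, n2) <= 8) {
      p <- vapply(seq_len(nrow(norm)), function(g) {
        suppressWarnings(stats::wilcox.test(norm[g, idx], norm[g, -idx],
                                            exact = TRUE,
                                            correct = FALSE)$p.value)
      }, numeric(1))
    } else {
      r1 <- rowSums(ranks[, idx, drop = FALSE])
      u <- r1 - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
      z <- ifelse(sigma2 > 0, (u - mu) / sqrt(sigma2), 0)
      p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    }
    p[is.na(p)] <- 1
    p_adj <- stats::p.adjust(p, method = "BH")
    specific <- p_adj < p_adj_cutoff & abs(log2fc) > log2fc_cutoff
    if (min_pct > 0) {
      pct_in <- rowMeans(norm[, idx, drop = FALSE] > 0)
      specific <- specific & pct_in >= min_pct
    }
    out[[ci]] <- data.frame(cluster = cl, gene = genes, log2fc = log2fc,
                            p = p, p_adj = p_adj, specific = specific,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-cluster sets of specific genes
#'
#' Extracts, for each cluster in a marker table, the genes flagged
#' `specific`, ordered by adjusted p then gene id.
#'
#' @param table a marker table from [rank_markers()].
#' @return Named list mapping cluster id to a character vector of genes.
#' @export
specific_gene_sets <- function(table) {
  if (nrow(table) == 0) return(stats::setNames(list(), character(0)))
  clusters <- sort(unique(table$cluster))
  sets <- lapply(clusters, function(cl) {
    sub <- table[table$cluster == cl & table$specific, , drop = FALSE]
    sub <- sub[order(sub$p_adj, sub$gene), , drop = FALSE]
    sub$gene
  })
  names(sets) <- as.character(clusters)
  sets
}
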