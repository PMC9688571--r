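#' Log-normalize a count matrix
#'
#' Library-size normalization to `scale_factor` counts per cell followed by
#' a natural-log `log1p` transform:
#' `x_gc = log(1 + scale_factor * count_gc / libsize_c)`.
#'
#' @param counts nonnegative genes x cells count matrix.
#' @param scale_factor target library size after normalization.
#' @return Genes x cells matrix of log-normalized values, with the scale
#'   factor stored in attribute `"scale_factor"`.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("lognormalize: counts must be nonnegative")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    bad <- colnames(counts)[libsize == 0]
    if (is.null(bad)) bad <- which(libsize == 0)
    stop("lognormalize: zero library size for cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- log1p(sweep(counts, 2, libsize / scale_factor, "/"))
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Drop genes with zero counts in every cell
#'
#' @param counts genes x cells count matrix.
#' @return The matrix restricted to expressed genes, original order kept.
#' @export
filter_unexpressed <- function(counts) {
  counts[rowSums(counts != 0) > 0, , drop = FALSE]
}

#' Select highly variable genes by the mean/dispersion-bin method
#'
#' Per gene, the mean and dispersion (variance / mean) of the de-logged
#' normalized values are computed; the mean is re-logged (`log1p`) for
#' binning and bounds, genes are cut into `n_bins` equal-width mean bins, and
#' dispersions are z-scored within each bin. Genes with a bin z-score at or
#' above `z_cutoff` and a mean inside `mean_bounds` are selected.
#'
#' @param norm log-normalized genes x cells matrix from [lognormalize()].
#' @param n_bins number of equal-width mean bins.
#' @param z_cutoff within-bin dispersion z-score threshold.
#' @param mean_bounds length-2 numeric, bounds on the `log1p` mean.
#' @return Character vector of selected gene ids (or row indices if the
#'   matrix is unnamed).
#' @export
select_hvg_mvp <- function(norm, n_bins = 20, z_cutoff = 1.0,
                           mean_bounds = c(0.0125, 8)) {
  expd <- expm1(norm)
  mu <- rowMeans(expd)
  v <- apply(expd, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  lmu <- log1p(mu)

  bins <- cut(lmu, breaks = n_bins, include.lowest = TRUE)
  z <- numeric(length(disp))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 2) {
      if (length(idx) > 0) {
        warning("select_hvg_mvp: bin ", b,
                " has fewer than 2 genes; its z-scores set to 0")
        z[idx] <- 0
      }
      next
    }
    s <- stats::sd(disp[idx])
    z[idx] <- if (s > 0) (disp[idx] - mean(disp[idx])) / s else 0
  }
  keep <- z >= z_cutoff & lmu >= mean_bounds[1] & lmu <= mean_bounds[2]
  ids <- rownames(norm)
  if (is.null(ids)) which(keep) else ids[keep]
}

#' Principal component embedding of cells
#'
#' Genes are standardized across cells (z-scored, clipped at +/-10) before
#' PCA; components are ordered by decreasing variance.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param hvgs gene ids (or row indices) to use as features.
#' @param n_components number of components to return.
#' @param clip absolute cap applied to standardized values.
#' @return List: `embedding` (cells x `n_components` scores) and `var_ratio`
#'   (variance ratios for all computed components).
#' @export
run_pca <- function(norm, hvgs, n_components = 20, clip = 10) {
  x <- norm[hvgs, , drop = FALSE]
  if (nrow(x) < 2) stop("run_pca: need at least 2 highly variable genes")
  if (n_components > min(dim(x))) {
    stop("run_pca: n_components exceeds min(genes, cells) = ", min(dim(x)))
  }
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  s[s == 0] <- 1
  xs <- pmin(pmax((x - mu) / s, -clip), clip)
  pc <- stats::prcomp(t(xs), center = TRUE, scale. = FALSE)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  list(embedding = pc$x[, seq_len(n_components), drop = FALSE],
       var_ratio = vr)
}

#' Choose the number of principal components at the variance elbow
#'
#' The smallest `n` whose cumulative variance ratio reaches `cum_threshold`
#' or whose next component contributes less than `marginal_threshold`,
#' whichever comes first.
#'
#' @param variance_ratios nonincreasing nonnegative variance ratios.
#' @param cum_threshold cumulative-variance stopping rule.
#' @param marginal_threshold marginal-gain stopping rule.
#' @return Integer number of components.
#' @export
choose_n_pcs_elbow <- function(variance_ratios, cum_threshold = 0.90,
                               marginal_threshold = 0.005) {
  vr <- as.numeric(variance_ratios)
  if (length(vr) == 0) stop("choose_n_pcs_elbow: empty variance ratios")
  cs <- cumsum(vr)
  for (n in seq_along(vr)) {
    if (cs[n] >= cum_threshold) return(n)
    if (n < length(vr) && vr[n + 1] < marginal_threshold) return(n)
  }
  length(vr)
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' A k-nearest-neighbor graph (Euclidean, neighbor sets include the cell
#' itself) is converted to a shared-nearest-neighbor graph whose edge weight
#' is the Jaccard overlap of the two neighbor sets; weights below `prune`
#' are dropped; communities are found by Louvain modularity optimization at
#' the given resolution. Singleton communities are merged into the cluster
#' with the nearest centroid. Cluster ids are contiguous from 1, ordered by
#' decreasing size.
#'
#' @param embedding cells x dims matrix (e.g. from [run_pca()]).
#' @param k neighbors per cell (including self).
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed for the community detection.
#' @param prune SNN Jaccard weights below this are removed.
#' @return List of class `"cluster_labeling"`: `labels` (integer per cell),
#'   `k_neighbors`, `resolution`.
#' @export
cluster_snn <- function(embedding, k = 20, resolution = 0.8, seed = 0L,
                        prune = 1 / 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop("cluster_snn: k must be smaller than the number of cells")

  d <- as.matrix(stats::dist(embedding))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  nb <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                             j = as.integer(t(nn)), x = 1,
                             dims = c(n, n))
  shared <- Matrix::tcrossprod(nb)
  sm <- Matrix::summary(shared)
  w <- sm$x / (2 * k - sm$x) # Jaccard: |A&B| / (|A|+|B|-|A&B|), |A|=|B|=k
  keepe <- w >= prune & sm$i != sm$j
  jac <- Matrix::sparseMatrix(i = sm$i[keepe], j = sm$j[keepe],
                              x = w[keepe], dims = c(n, n))

  # jac is symmetric by construction; mode = "max" avoids igraph's
  # symmetry check on general sparse matrices
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max",
                                           weighted = TRUE)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))

  # merge singleton communities into the nearest cluster by centroid distance
  tab <- table(labels)
  singles <- as.integer(names(tab)[tab == 1])
  if (length(singles) && length(tab) > length(singles)) {
    keep <- as.integer(names(tab)[tab > 1])
    cent <- t(vapply(keep, function(cl) {
      colMeans(embedding[labels == cl, , drop = FALSE])
    }, numeric(ncol(embedding))))
    for (cl in singles) {
      i <- which(labels == cl)
      dd <- rowSums((cent - matrix(embedding[i, ], nrow(cent),
                                   ncol(embedding), byrow = TRUE))^2)
      labels[i] <- keep[which.min(dd)]
    }
  }

  # contiguous ids from 1, ordered by decreasing size (ties: first occurrence)
  tab <- table(labels)
  ord <- names(sort(tab, decreasing = TRUE))
  relabel <- stats::setNames(seq_along(ord), ord)
  labels <- as.integer(relabel[as.character(labels)])

  structure(list(labels = labels, k_neighbors = k, resolution = resolution),
            class = "cluster_labeling")
}
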