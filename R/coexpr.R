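#' Filter genes by median absolute deviation
#'
#' Keeps genes whose plain MAD (median of absolute deviations from the
#' median, no consistency constant) strictly exceeds `mad_threshold`.
#'
#' @param expr genes x cells expression matrix.
#' @param mad_threshold keep genes with MAD strictly greater than this.
#' @return The filtered matrix, gene order preserved.
#' @export
filter_genes_mad <- function(expr, mad_threshold = 0) {
  mads <- apply(expr, 1, stats::mad, constant = 1)
  expr[mads > mad_threshold, , drop = FALSE]
}

#' Soft-threshold co-expression adjacency
#'
#' Unsigned weighted adjacency `a_ij = |cor(x_i, x_j)|^beta` with unit
#' diagonal.
#'
#' @param expr genes x cells matrix (at least 2 genes, 3 cells).
#' @param beta soft-threshold power.
#' @return Symmetric genes x genes adjacency in `[0, 1]`.
#' @export
soft_threshold_adjacency <- function(expr, beta = 6) {
  if (nrow(expr) < 2 || ncol(expr) < 3) {
    stop("soft_threshold_adjacency: need >= 2 genes and >= 3 cells")
  }
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    stop("soft_threshold_adjacency: zero-variance gene(s); ",
         "filter them first (e.g. filter_genes_mad)")
  }
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i` is the connectivity (row sum
#' minus the diagonal). Diagonal is 1.
#'
#' @param adjacency symmetric adjacency from [soft_threshold_adjacency()].
#' @return Symmetric genes x genes TOM in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  k <- rowSums(a) - diag(a)
  num <- a %*% a - a # (A^2)_ij counts u=i and u=j, each contributing a_ij
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (`1 - TOM`), cut at a fixed height; clusters smaller than `min_size` are
#' labeled `"grey"` (unassigned), the rest get color labels by decreasing
#' size.
#'
#' @param tom TOM from [tom_similarity()].
#' @param cut_height static cut height on `1 - TOM`.
#' @param min_size minimum module size.
#' @return Character vector of module labels, named by gene.
#' @export
detect_modules <- function(tom, cut_height = 0.25, min_size = 10) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  tab <- sort(table(cl), decreasing = TRUE)
  big <- names(tab)[tab >= min_size]
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple")
  labels <- rep("grey", length(cl))
  for (i in seq_along(big)) {
    labels[cl == as.integer(big[i])] <- if (i <= length(palette)) {
      palette[i]
    } else paste0("module", i)
  }
  nm <- rownames(as.matrix(tom))
  if (is.null(nm)) nm <- as.character(seq_along(cl))
  stats::setNames(labels, nm)
}

#' Build a co-expression network object
#'
#' Convenience wrapper chaining [filter_genes_mad()],
#' [soft_threshold_adjacency()], [tom_similarity()] and [detect_modules()].
#'
#' @param expr genes x cells expression matrix.
#' @param beta soft-threshold power.
#' @param mad_threshold MAD filter threshold.
#' @param cut_height,min_size module detection parameters.
#' @return List of class `"coexpr_network"`: `genes`, `adjacency`, `tom`,
#'   `module`.
#' @export
build_coexpr_network <- function(expr, beta = 6, mad_threshold = 0,
                                 cut_height = 0.25, min_size = 10) {
  expr <- filter_genes_mad(expr, mad_threshold)
  adj <- soft_threshold_adjacency(expr, beta = beta)
  tom <- tom_similarity(adj)
  module <- detect_modules(tom, cut_height = cut_height, min_size = min_size)
  structure(list(genes = rownames(expr), adjacency = adj, tom = tom,
                 module = module),
            class = "coexpr_network")
}

#' Pick a soft-threshold power by scale-free topology fit
#'
#' For each candidate power, the R-squared of the log-log regression of
#' degree frequency on degree (scale-free fit) is computed; the smallest
#' power reaching `target_r2` is returned (or the power with the best fit).
#'
#' @param expr genes x cells matrix.
#' @param powers candidate powers.
#' @param target_r2 R-squared considered an adequate scale-free fit.
#' @param n_breaks histogram bins for the degree distribution.
#' @return List `power`, `fit` (data.frame `power`, `r_squared`).
#' @export
pick_soft_threshold <- function(expr, powers = 1:12, target_r2 = 0.8,
                                n_breaks = 10) {
  cors <- abs(stats::cor(t(expr)))
  diag(cors) <- 0
  fit <- vapply(powers, function(beta) {
    k <- rowSums(cors^beta)
    if (diff(range(k)) == 0) return(0)
    cuts <- cut(k, n_breaks)
    dk <- tapply(k, cuts, mean)
    pk <- as.numeric(table(cuts)) / length(k)
    ok <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(ok) < 3) return(0)
    summary(stats::lm(log10(pk[ok]) ~ log10(dk[ok])))$r.squared
  }, numeric(1))
  hit <- which(fit >= target_r2)
  power <- if (length(hit)) powers[hit[1]] else powers[which.max(fit)]
  list(power = power, fit = data.frame(power = powers, r_squared = fit))
}

#' Hub genes by retained-edge degree
#'
#' Grey-module genes are removed; the remaining gene-gene edges are ranked
#' by adjacency weight and the top `top_edge_fraction` retained
#' (`ceiling(fraction x candidate edges)`); node degree is the number of
#' retained incident edges. Returns the top `k` genes by degree, ties broken
#' by summed retained weight then gene id.
#'
#' @param network a `"coexpr_network"` from [build_coexpr_network()].
#' @param top_edge_fraction fraction of non-grey edges to retain.
#' @param k number of hub genes to return.
#' @return List: `hubs` (character, length <= k), `degree` (named integer
#'   over non-grey genes), `retained_edges` (data.frame `from`, `to`,
#'   `weight`, ordered by decreasing weight).
#' @export
hub_genes <- function(network, top_edge_fraction = 0.01, k = 2) {
  stopifnot(inherits(network, "coexpr_network"))
  keep <- names(network$module)[network$module != "grey"]
  if (!length(keep)) stop("hub_genes: no gene outside the grey module")
  if (length(keep) < 2) {
    warning("hub_genes: fewer than 2 non-grey genes; no edges to retain")
    return(list(hubs = character(0),
                degree = stats::setNames(integer(length(keep)), keep),
                retained_edges = data.frame(from = character(0),
                                            to = character(0),
                                            weight = numeric(0))))
  }
  a <- network$adjacency[keep, keep]
  ut <- which(upper.tri(a), arr.ind = TRUE)
  ew <- a[ut]
  n_edges <- nrow(ut)
  m <- ceiling(top_edge_fraction * n_edges)
  ord <- order(-ew, ut[, 1], ut[, 2])[seq_len(m)]
  edges <- data.frame(from = keep[ut[ord, 1]], to = keep[ut[ord, 2]],
                      weight = ew[ord], stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(length(keep)), keep)
  wsum <- stats::setNames(numeric(length(keep)), keep)
  for (i in seq_len(nrow(edges))) {
    deg[edges$from[i]] <- deg[edges$from[i]] + 1L
    deg[edges$to[i]] <- deg[edges$to[i]] + 1L
    wsum[edges$from[i]] <- wsum[edges$from[i]] + edges$weight[i]
    wsum[edges$to[i]] <- wsum[edges$to[i]] + edges$weight[i]
  }
  rank_ord <- order(-deg, -wsum, keep)
  list(hubs = keep[rank_ord[seq_len(min(k, length(keep)))]],
       degree = deg, retained_edges = edges)
}
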