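#' Fit a principal tree through cluster centroids
#'
#' A deliberately simple principal-tree trajectory: tree nodes are the
#' cluster centroids in the embedding, edges are the Euclidean minimum
#' spanning tree over centroids, and every cell is projected orthogonally
#' onto its nearest tree edge. Projection ties between equidistant edges are
#' broken by the lower edge index.
#'
#' @param embedding cells x dims matrix.
#' @param labels cluster id per cell.
#' @return Unrooted `"trajectory_model"`: `node_coords` (clusters x dims,
#'   rownames = cluster ids), `edges` (data.frame `from`, `to`, `length`,
#'   node indices with `from < to`), `branch_points` (node indices of degree
#'   >= 3), `cell_edge`, `cell_offset` (position along the edge in `[0,1]`,
#'   measured from `from`), `labels`.
#' @export
fit_principal_tree <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  if (is.factor(labels)) labels <- as.character(labels)
  clusters <- sort(unique(labels))
  k <- length(clusters)
  if (k < 2) {
    stop("fit_principal_tree: need at least 2 clusters; with one cluster ",
         "use a linear pseudotime (e.g. the first embedding component)")
  }
  cent <- t(vapply(clusters, function(cl) {
    colMeans(embedding[labels == cl, , drop = FALSE])
  }, numeric(ncol(embedding))))
  rownames(cent) <- as.character(clusters)

  d <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(mst, names = FALSE)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      length = d[el])

  n <- nrow(embedding)
  best_d <- rep(Inf, n)
  cell_edge <- integer(n)
  cell_offset <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    a <- cent[edges$from[e], ]
    b <- cent[edges$to[e], ]
    ab <- b - a
    len2 <- sum(ab^2)
    diff <- sweep(embedding, 2, a)
    tt <- if (len2 > 0) pmin(1, pmax(0, as.numeric(diff %*% ab) / len2)) else
      rep(0, n)
    proj_d <- rowSums((diff - outer(tt, ab))^2)
    upd <- proj_d < best_d - 1e-12
    best_d[upd] <- proj_d[upd]
    cell_edge[upd] <- e
    cell_offset[upd] <- tt[upd]
  }

  deg <- tabulate(c(edges$from, edges$to), nbins = k)
  structure(list(node_coords = cent, edges = edges,
                 branch_points = which(deg >= 3),
                 cell_edge = cell_edge, cell_offset = cell_offset,
                 labels = labels),
            class = "trajectory_model")
}

#' Root a principal tree and assign pseudotime and states
#'
#' Pseudotime of a cell is the geodesic (along-tree) distance from the root
#' node to the cell's projected point. States are the maximal unbranched
#' segments of the tree (edges grouped between nodes of degree != 2),
#' numbered by discovery order from the root.
#'
#' @param model an unrooted `"trajectory_model"` from [fit_principal_tree()].
#' @param root_cluster cluster id to use as the root node.
#' @return The model with `root`, `pseudotime` (per cell, >= 0), `state`
#'   (integer per cell) and `node_time` (geodesic distance per node) added.
#' @export
root_and_time <- function(model, root_cluster) {
  stopifnot(inherits(model, "trajectory_model"))
  nodes <- rownames(model$node_coords)
  root <- match(as.character(root_cluster), nodes)
  if (is.na(root)) {
    stop("root_and_time: unknown root cluster '", root_cluster,
         "'; valid roots: ", paste(nodes, collapse = ", "))
  }
  k <- nrow(model$node_coords)
  g <- igraph::graph_from_data_frame(
    data.frame(from = model$edges$from, to = model$edges$to,
               weight = model$edges$length),
    directed = FALSE, vertices = data.frame(name = seq_len(k)))
  node_time <- as.numeric(igraph::distances(g, v = as.character(root))[1, ])

  e_from <- model$edges$from
  e_to <- model$edges$to
  e_len <- model$edges$length
  # parent endpoint of each edge = the one nearer the root along the tree
  from_is_parent <- node_time[e_from] <= node_time[e_to]

  off <- model$cell_offset
  ed <- model$cell_edge
  pt <- ifelse(from_is_parent[ed],
               node_time[e_from[ed]] + off * e_len[ed],
               node_time[e_to[ed]] + (1 - off) * e_len[ed])

  # maximal unbranched segments: consecutive edges merge across degree-2 nodes
  deg <- tabulate(c(e_from, e_to), nbins = k)
  seg_of_edge <- integer(nrow(model$edges))
  seg <- 0L
  # discovery order from the root: BFS over edges
  adj <- lapply(seq_len(k), function(v) which(e_from == v | e_to == v))
  visited <- rep(FALSE, nrow(model$edges))
  root_seg <- 0L # a degree-2 root is interior to a single unbranched segment
  queue <- list() # entries: c(edge, entry_node, segment)
  for (e in adj[[root]]) queue[[length(queue) + 1]] <- c(e, root, 0L)
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    e <- item[1]; entry <- item[2]; cur_seg <- item[3]
    if (visited[e]) next
    visited[e] <- TRUE
    # start a new segment unless we entered through an unbranched interior node
    if (cur_seg == 0L && deg[entry] == 2 && root_seg > 0L) {
      seg_of_edge[e] <- root_seg
    } else if (cur_seg == 0L || deg[entry] != 2) {
      seg <- seg + 1L
      seg_of_edge[e] <- seg
      if (cur_seg == 0L && deg[entry] == 2) root_seg <- seg
    } else {
      seg_of_edge[e] <- cur_seg
    }
    other <- if (e_from[e] == entry) e_to[e] else e_from[e]
    for (e2 in adj[[other]]) {
      if (!visited[e2]) queue[[length(queue) + 1]] <- c(e2, other,
                                                        seg_of_edge[e])
    }
  }
  model$root <- root
  model$node_time <- node_time
  model$pseudotime <- as.numeric(pt)
  model$state <- seg_of_edge[ed]
  model$segment_of_edge <- seg_of_edge
  model
}

#' Mean pseudotime per cluster
#'
#' @param pseudotime numeric pseudotime per cell.
#' @param labels cluster id per cell.
#' @return Named numeric vector, one mean per non-empty cluster; empty
#'   clusters (unused factor levels) are dropped with a warning.
#' @export
cluster_mean_pseudotime <- function(pseudotime, labels) {
  stopifnot(length(pseudotime) == length(labels))
  if (is.factor(labels) && any(table(labels) == 0)) {
    warning("cluster_mean_pseudotime: empty cluster(s) excluded: ",
            paste(names(which(table(labels) == 0)), collapse = ", "))
  }
  out <- tapply(pseudotime, as.character(labels), mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Smooth expression trend of one gene over pseudotime
#'
#' Least-squares fit of expression on a natural cubic spline basis of
#' pseudotime with `df` degrees of freedom, evaluated on a 100-point grid
#' over the observed pseudotime range.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param pseudotime numeric per cell.
#' @param gene gene id (rowname) or row index.
#' @param df spline degrees of freedom.
#' @return data.frame `t`, `fitted` with 100 rows.
#' @export
gene_trend <- function(norm, pseudotime, gene, df = 3) {
  y <- as.numeric(norm[gene, ])
  x <- as.numeric(pseudotime)
  if (length(x) < df + 2) stop("gene_trend: need at least df + 2 cells")
  if (diff(range(x)) == 0) stop("gene_trend: pseudotime is constant")
  basis <- splines::ns(x, df = df)
  fit <- stats::lm(y ~ basis)
  grid <- seq(min(x), max(x), length.out = 100)
  fitted <- cbind(1, stats::predict(basis, grid)) %*% stats::coef(fit)
  data.frame(t = grid, fitted = as.numeric(fitted))
}
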