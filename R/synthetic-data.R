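#' Simulation configuration for the synthetic study
#'
#' Builds the configuration object consumed by [simulate_cells()] and
#' [simulate_bulk()]. The generator emulates the statistical structure the
#' analysis chain assumes: two cohorts of cells drawn from clusters arranged
#' along a branching latent trajectory with cluster-specific marker genes,
#' bulk samples formed as noisy mixtures of cluster expression profiles, and
#' survival times whose hazard increases with the true patient pseudotime
#' score.
#'
#' Cluster centers sit at integer depths of `topology` (root = cluster 1,
#' unit edge lengths); a cell's latent time is its cluster depth plus a
#' uniform jitter of half an edge, rescaled to `[0, 1]`. The topology is also
#' embedded in a low-dimensional latent space (one random unit direction per
#' edge); `n_gradient_genes` genes load linearly on that latent position so
#' that expression distance between clusters reflects trajectory distance.
#' Marker genes are discrete: mean expression multiplied by
#' `2^marker_log2fc` in the owning cluster only.
#'
#' @param n_genes number of genes.
#' @param n_cells number of cells.
#' @param n_clusters number of cell clusters.
#' @param topology two-column integer matrix of undirected edges over cluster
#'   ids `1..n_clusters`; must be a connected acyclic graph (a tree).
#' @param markers_per_cluster planted marker genes per cluster.
#' @param marker_log2fc log2 fold change of a marker in its own cluster.
#' @param n_gradient_genes genes whose expression varies smoothly along the
#'   latent trajectory (gives cluster centroids their tree geometry).
#' @param gradient_log2fc log2-scale amplitude per unit latent coordinate for
#'   gradient genes.
#' @param libsize_mean expected library size (total counts per cell).
#' @param libsize_sdlog log-normal sdlog of library size variation.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); shared across genes.
#' @param n_patients number of bulk samples / patients.
#' @param bulk_noise_sd Gaussian noise added to bulk expression, expressed as
#'   a fraction of each gene's mean cluster-profile signal (0.1 = 10\% of
#'   signal).
#' @param proportion_alpha symmetric Dirichlet concentration for bulk mixing
#'   proportions; values < 1 give samples dominated by one or few clusters,
#'   as in real tumors.
#' @param baseline_hazard exponential baseline hazard, events per day.
#' @param score_log_hazard_ratio log hazard ratio per unit of the true
#'   patient pseudotime score (score lies in `[0, 1]`).
#' @param censor_rate rate per day of the independent exponential censoring
#'   time; the default gives roughly 30\% censoring under the default hazard.
#' @param n_cohorts number of cell cohorts (e.g. adult/child); cells are
#'   assigned to samples, samples split evenly across cohorts.
#' @param samples_per_cohort single-cell samples per cohort.
#' @param seed integer seed; a fixed seed makes every output bit-identical.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_cells = 1000, n_clusters = 5,
                       topology = default_topology(n_clusters),
                       markers_per_cluster = 50, marker_log2fc = 2,
                       n_gradient_genes = 200, gradient_log2fc = 2,
                       libsize_mean = 5000, libsize_sdlog = 0.3,
                       nb_dispersion = 0.3,
                       n_patients = 150, bulk_noise_sd = 0.1,
                       proportion_alpha = 0.3,
                       baseline_hazard = log(2) / 430,
                       score_log_hazard_ratio = 1,
                       censor_rate = 7e-4,
                       n_cohorts = 2, samples_per_cohort = 4,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_clusters = as.integer(n_clusters), topology = as.matrix(topology),
    markers_per_cluster = as.integer(markers_per_cluster),
    marker_log2fc = marker_log2fc,
    n_gradient_genes = as.integer(n_gradient_genes),
    gradient_log2fc = gradient_log2fc,
    libsize_mean = libsize_mean, libsize_sdlog = libsize_sdlog,
    nb_dispersion = nb_dispersion,
    n_patients = as.integer(n_patients), bulk_noise_sd = bulk_noise_sd,
    proportion_alpha = proportion_alpha,
    baseline_hazard = baseline_hazard,
    score_log_hazard_ratio = score_log_hazard_ratio,
    censor_rate = censor_rate,
    n_cohorts = as.integer(n_cohorts),
    samples_per_cohort = as.integer(samples_per_cohort),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default branching topology over clusters
#'
#' A rooted binary-tree edge list (node `i` attaches to `floor(i/2)`), which
#' for five clusters yields a trajectory with one branch point.
#'
#' @param n_clusters number of clusters (>= 1).
#' @return Two-column integer matrix of edges (empty for one cluster).
#' @export
default_topology <- function(n_clusters) {
  if (n_clusters < 2) return(matrix(integer(0), ncol = 2))
  cbind(pmax(1L, as.integer(floor(seq(2, n_clusters) / 2))),
        seq(2L, as.integer(n_clusters)))
}

validate_sim_config <- function(cfg) {
  pos <- c("n_genes", "n_cells", "n_clusters", "markers_per_cluster",
           "libsize_mean", "nb_dispersion", "n_patients", "n_cohorts",
           "samples_per_cohort", "baseline_hazard")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("sim_config: '", f, "' must be a single positive number")
    }
  }
  k <- cfg$n_clusters
  topo <- cfg$topology
  if (k >= 2) {
    if (ncol(topo) != 2 || nrow(topo) != k - 1) {
      stop("sim_config: topology must be a tree with ", k - 1,
           " edges over ", k, " clusters")
    }
    g <- igraph::graph_from_edgelist(topo, directed = FALSE)
    if (igraph::vcount(g) != k || !igraph::is_connected(g) ||
        igraph::ecount(g) != k - 1 || any(igraph::which_loop(g))) {
      stop("sim_config: topology must be a connected acyclic graph on ",
           k, " clusters")
    }
  }
  needed <- cfg$n_clusters * cfg$markers_per_cluster + cfg$n_gradient_genes
  if (needed > cfg$n_genes) {
    stop("sim_config: n_genes too small for planted markers and gradient genes")
  }
  invisible(cfg)
}

# Tree helpers on the cluster topology: depths from root (cluster 1) and the
# per-cluster latent-space coordinates (one random unit direction per edge).
topology_depths <- function(topo, k) {
  if (k == 1) return(0)
  g <- igraph::graph_from_edgelist(topo, directed = FALSE)
  as.numeric(igraph::distances(g, v = 1)[1, seq_len(k)])
}

#' Simulate single-cell counts with planted ground truth
#'
#' Draws negative-binomial counts for `n_cells` cells from `n_clusters`
#' clusters arranged along the configured trajectory. Gene-level base
#' abundances are log-normal; marker genes are amplified `2^marker_log2fc`-fold
#' in their own cluster; gradient genes vary smoothly with each cell's
#' position on the latent tree.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"sc_dataset"` with elements `counts` (genes x
#'   cells integer matrix), `meta` (data.frame: `cell_id`, `sample_id`,
#'   `cohort`, `cluster_true`, `latent_time`) and `truth` (class
#'   `"sim_truth"`): `cell_cluster`, `cell_latent_time`, `marker_genes`
#'   (list per cluster), `gradient_genes`, `cluster_latent_mean`, plus the
#'   latent coordinates used.
#' @export
simulate_cells <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; nc <- config$n_cells; k <- config$n_clusters

  cluster <- sample.int(k, nc, replace = TRUE)
  # guarantee every cluster is populated (tiny n could miss one)
  missing <- setdiff(seq_len(k), unique(cluster))
  if (length(missing)) cluster[seq_along(missing)] <- missing

  depths <- topology_depths(config$topology, k)
  max_depth <- max(depths, 1)

  # latent embedding of the topology: each edge gets its own orthogonal
  # axis, so Euclidean distance between nodes grows monotonically with
  # tree distance (adjacent = 1, two edges apart = sqrt(2), ...)
  lat_dim <- max(1L, k - 1L)
  node_lat <- matrix(0, k, lat_dim)
  parent <- rep(NA_integer_, k)
  if (k >= 2) {
    g <- igraph::graph_from_edgelist(config$topology, directed = FALSE)
    bfs <- igraph::bfs(g, root = 1, father = TRUE)
    parent <- as.integer(bfs$father)
    ord <- as.integer(bfs$order)
    for (ei in seq_along(ord[-1])) {
      v <- ord[-1][ei]
      node_lat[v, ] <- node_lat[parent[v], ]
      node_lat[v, ei] <- node_lat[v, ei] + 1
    }
  }
  children <- lapply(seq_len(k), function(v) which(parent == v))

  # within-cluster jitter of +/- half an edge, placed on a parent or child edge
  jitter <- runif(nc, -0.5, 0.5)
  pos_depth <- numeric(nc)
  cell_lat <- matrix(0, nc, lat_dim)
  for (i in seq_len(nc)) {
    c_i <- cluster[i]; j <- jitter[i]
    if (j < 0) {
      if (!is.na(parent[c_i])) {
        pos_depth[i] <- depths[c_i] + j
        w <- -j # fraction of the way toward the parent
        cell_lat[i, ] <- (1 - w) * node_lat[c_i, ] + w * node_lat[parent[c_i], ]
      } else { # root cluster has no parent edge
        pos_depth[i] <- depths[c_i]
        cell_lat[i, ] <- node_lat[c_i, ]
      }
    } else {
      kids <- children[[c_i]]
      if (length(kids)) {
        ch <- if (length(kids) == 1) kids else kids[sample.int(length(kids), 1)]
        pos_depth[i] <- depths[c_i] + j
        cell_lat[i, ] <- (1 - j) * node_lat[c_i, ] + j * node_lat[ch, ]
      } else { # leaf cluster has no child edge
        pos_depth[i] <- depths[c_i]
        cell_lat[i, ] <- node_lat[c_i, ]
      }
    }
  }
  latent_time <- pmin(1, pmax(0, pos_depth / max_depth))

  gene_ids <- sprintf("gene%04d", seq_len(ng))
  mpc <- config$markers_per_cluster
  marker_genes <- lapply(seq_len(k), function(c_i) {
    gene_ids[((c_i - 1) * mpc + 1):(c_i * mpc)]
  })
  names(marker_genes) <- as.character(seq_len(k))
  grad_idx <- if (config$n_gradient_genes > 0) {
    k * mpc + seq_len(config$n_gradient_genes)
  } else integer(0)

  lambda <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)
  log2mult <- matrix(0, ng, nc)
  for (c_i in seq_len(k)) {
    g_idx <- ((c_i - 1) * mpc + 1):(c_i * mpc)
    log2mult[g_idx, cluster == c_i] <- config$marker_log2fc
  }
  if (length(grad_idx)) {
    loadings <- matrix(rnorm(length(grad_idx) * lat_dim), ncol = lat_dim)
    loadings <- loadings / sqrt(rowSums(loadings^2))
    log2mult[grad_idx, ] <- log2mult[grad_idx, ] +
      config$gradient_log2fc * (loadings %*% t(cell_lat))
  }

  mu_rel <- lambda * 2^log2mult
  mu_rel <- sweep(mu_rel, 2, colSums(mu_rel), "/")
  libsize <- stats::rlnorm(nc, meanlog = log(config$libsize_mean) -
                             config$libsize_sdlog^2 / 2,
                           sdlog = config$libsize_sdlog)
  mu <- sweep(mu_rel, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(ng * nc, mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = ng,
                   dimnames = list(gene_ids,
                                   sprintf("cell%05d", seq_len(nc))))

  n_samples <- config$n_cohorts * config$samples_per_cohort
  sample_id <- sprintf("S%02d", sample.int(n_samples, nc, replace = TRUE))
  cohort_of_sample <- rep(paste0("cohort", seq_len(config$n_cohorts)),
                          each = config$samples_per_cohort)
  names(cohort_of_sample) <- sprintf("S%02d", seq_len(n_samples))
  meta <- data.frame(
    cell_id = colnames(counts),
    sample_id = sample_id,
    cohort = unname(cohort_of_sample[sample_id]),
    cluster_true = cluster,
    latent_time = latent_time,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    cell_cluster = cluster,
    cell_latent_time = latent_time,
    marker_genes = marker_genes,
    gradient_genes = gene_ids[grad_idx],
    cluster_latent_mean = as.numeric(tapply(latent_time, cluster, mean)),
    node_latent = node_lat,
    cell_latent = cell_lat
  ), class = "sim_truth")
  names(truth$cluster_latent_mean) <- as.character(seq_len(k))

  structure(list(counts = counts, meta = meta, truth = truth,
                 config = config),
            class = "sc_dataset")
}

#' Simulate bulk expression mixtures and survival outcomes
#'
#' Bulk sample `b` is `sum_c w_bc * profile(c)` plus Gaussian noise, where
#' `profile(c)` is the empirical mean count profile of cluster `c` and the
#' mixing weights `w` are Dirichlet-distributed. The true patient score is
#' `sum_c w_bc * mean latent time(c)`; survival times are exponential with
#' log-hazard `log(baseline_hazard) + score_log_hazard_ratio * score`, with
#' independent exponential censoring.
#'
#' @param sc an `"sc_dataset"` from [simulate_cells()].
#' @param config a [sim_config()]; defaults to the one stored in `sc`.
#' @param seed optional seed for the bulk stage; defaults to
#'   `config$seed + 1` so cells and bulk use distinct streams.
#' @return A list of class `"bulk_dataset"`: `bulk` (genes x samples),
#'   `survival` (data.frame `sample_id`, `time_days`, `event`),
#'   `true_proportions` (samples x clusters, rows sum to 1),
#'   `true_score` (named numeric) and `profiles` (genes x clusters).
#' @export
simulate_bulk <- function(sc, config = sc$config, seed = config$seed + 1L) {
  stopifnot(inherits(sc, "sc_dataset"))
  set.seed(as.integer(seed))
  k <- config$n_clusters
  cluster <- sc$truth$cell_cluster
  profiles <- vapply(seq_len(k), function(c_i) {
    rowMeans(sc$counts[, cluster == c_i, drop = FALSE])
  }, numeric(nrow(sc$counts)))
  colnames(profiles) <- as.character(seq_len(k))

  np <- config$n_patients
  w <- matrix(stats::rgamma(np * k, shape = config$proportion_alpha), np, k)
  w <- w / rowSums(w)
  dimnames(w) <- list(sprintf("P%03d", seq_len(np)), as.character(seq_len(k)))

  bulk <- profiles %*% t(w)
  if (config$bulk_noise_sd > 0) {
    sd_g <- config$bulk_noise_sd * rowMeans(profiles)
    bulk <- bulk + matrix(rnorm(length(bulk)), nrow(bulk)) * sd_g
    bulk <- pmax(bulk, 0)
  }
  colnames(bulk) <- rownames(w)

  tau <- sc$truth$cluster_latent_mean[colnames(w)]
  score <- as.numeric(w %*% tau)
  names(score) <- rownames(w)

  rate <- config$baseline_hazard * exp(config$score_log_hazard_ratio * score)
  t_event <- stats::rexp(np, rate)
  t_cens <- if (config$censor_rate > 0) stats::rexp(np, config$censor_rate) else Inf
  survival <- data.frame(
    sample_id = rownames(w),
    time_days = pmax(pmin(t_event, t_cens), 1e-3),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )

  structure(list(bulk = bulk, survival = survival,
                 true_proportions = w, true_score = score,
                 profiles = profiles),
            class = "bulk_dataset")
}

#' Write a synthetic study to disk in standard plain-text formats
#'
#' Counts go to MatrixMarket `matrix.mtx` with `genes.tsv`/`barcodes.tsv`
#' companions (CellRanger dialect), cell metadata to `metadata.csv`, bulk
#' expression to `bulk.tsv` (genes x samples, header row) and survival to
#' `survival.csv` (`sample_id,time_days,event`). Round-trips losslessly
#' through [read_sc_dataset()], [read_bulk_tsv()] and [read_survival_csv()].
#'
#' @param dir output directory (created if needed).
#' @param sc an `"sc_dataset"` (required).
#' @param bulk an optional `"bulk_dataset"`.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dir, sc, bulk = NULL) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (length(sc$counts) == 0 || nrow(sc$counts) == 0 || ncol(sc$counts) == 0) {
    stop("write_dataset: empty count matrix; refusing to write empty files")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  m <- Matrix::Matrix(sc$counts, sparse = TRUE)
  p <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, p)
  files <- c(files, p)
  utils::write.table(data.frame(gene = rownames(sc$counts)),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(barcode = colnames(sc$counts)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(sc$meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  files <- c(files, file.path(dir, c("genes.tsv", "barcodes.tsv",
                                     "metadata.csv")))
  if (!is.null(bulk)) {
    stopifnot(inherits(bulk, "bulk_dataset"))
    bt <- data.frame(gene = rownames(bulk$bulk), bulk$bulk,
                     check.names = FALSE)
    utils::write.table(bt, file.path(dir, "bulk.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(bulk$survival, file.path(dir, "survival.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(dir, c("bulk.tsv", "survival.csv")))
  }
  invisible(files)
}

#' Read a single-cell dataset written by [write_dataset()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `metadata.csv`.
#' @return A list of class `"sc_dataset"` with `counts` and `meta` (NULL if
#'   no metadata file is present).
#' @export
read_sc_dataset <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  dimnames(m) <- list(genes, cells)
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (file.exists(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(counts = m, meta = meta, truth = NULL, config = NULL),
            class = "sc_dataset")
}

#' Read a bulk expression TSV (genes x samples, first column = gene id)
#' @param path path to the TSV.
#' @return Numeric matrix, genes x samples.
#' @export
read_bulk_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Read a survival CSV with columns sample_id, time_days, event
#' @param path path to the CSV.
#' @return data.frame with those columns.
#' @export
read_survival_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time_days", "event") %in% names(d)))
  d
}

#' Simulate planted co-expression blocks with designated hub genes
#'
#' Generates an expression matrix of `n_blocks` tightly correlated gene
#' blocks plus independent background genes, for validating the
#' co-expression network stage. Within a block, every gene loads on a shared
#' latent factor; the first gene of each block (the hub) has a higher
#' loading, giving it the strongest correlations and hence the highest
#' retained-edge degree.
#'
#' @param n_blocks number of planted modules.
#' @param genes_per_block genes per module (first gene of each block = hub).
#' @param n_background independent noise genes (true "grey" genes).
#' @param n_cells number of cells (columns).
#' @param member_loading latent-factor loading of non-hub block genes.
#' @param hub_loading latent-factor loading of the hub gene.
#' @param seed integer seed.
#' @return List: `expr` (genes x cells), `block` (integer label per gene, 0 =
#'   background), `hubs` (character vector of planted hub gene ids).
#' @export
simulate_coexpr <- function(n_blocks = 2, genes_per_block = 150,
                            n_background = 100, n_cells = 300,
                            member_loading = 0.985, hub_loading = 0.998,
                            seed = 1L) {
  set.seed(as.integer(seed))
  ng <- n_blocks * genes_per_block + n_background
  expr <- matrix(0, ng, n_cells)
  block <- integer(ng)
  hubs <- character(n_blocks)
  row <- 1L
  for (b in seq_len(n_blocks)) {
    f <- rnorm(n_cells)
    for (j in seq_len(genes_per_block)) {
      a <- if (j == 1) hub_loading else member_loading
      expr[row, ] <- a * f + sqrt(1 - a^2) * rnorm(n_cells)
      block[row] <- b
      if (j == 1) hubs[b] <- sprintf("g%03d", row)
      row <- row + 1L
    }
  }
  if (n_background > 0) {
    expr[row:ng, ] <- matrix(rnorm(n_background * n_cells), n_background)
  }
  rownames(expr) <- sprintf("g%03d", seq_len(ng))
  colnames(expr) <- sprintf("cell%04d", seq_len(n_cells))
  list(expr = expr, block = block, hubs = hubs)
}
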