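#' Run the full synthetic-study analysis pipeline
#'
#' Generates a seeded synthetic study (two single-cell cohorts, bulk
#' mixtures, survival) and runs the complete chain: normalization, highly
#' variable gene selection, PCA with elbow selection, SNN clustering, marker
#' detection, cross-cohort Jaccard matching, principal-tree pseudotime,
#' signature-based deconvolution (SVR and NNLS), patient pseudotime scores,
#' prognosis-group content comparison, optimal-cutpoint survival
#' stratification and the co-expression hub stage on the key (latest
#' pseudotime) cluster. All outputs are plain text and fully determined by
#' the seed.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()]; its seed is overridden by `seed`.
#' @param seed integer master seed.
#' @param root_cluster trajectory root (inferred-cluster id); default is the
#'   leaf cluster with the lowest id.
#' @param key_cluster cluster for the co-expression stage; default is the
#'   cluster with the highest mean pseudotime that has enough cells and
#'   specific genes.
#' @param n_perm permutations for the adjusted cutpoint p (0 = naive only).
#' @return Invisibly, a list with the intermediate results and the vector of
#'   files written.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = config$seed,
                         root_cluster = NULL, key_cluster = NULL,
                         n_perm = 0) {
  config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sc <- simulate_cells(config)
  bulk <- simulate_bulk(sc, config)
  write_dataset(file.path(out_dir, "data"), sc, bulk)

  cohorts <- sort(unique(sc$meta$cohort))
  per_cohort <- list()
  for (co in cohorts) {
    idx <- which(sc$meta$cohort == co)
    counts <- filter_unexpressed(sc$counts[, idx, drop = FALSE])
    norm <- lognormalize(counts)
    hvgs <- select_hvg_mvp(norm)
    if (length(hvgs) < 10) hvgs <- rownames(norm) # tiny runs: use all genes
    n_comp <- min(30, length(hvgs) - 1, ncol(norm) - 1)
    pca <- run_pca(norm, hvgs, n_components = n_comp)
    npc <- min(n_comp, choose_n_pcs_elbow(pca$var_ratio))
    emb <- pca$embedding[, seq_len(npc), drop = FALSE]
    cl <- cluster_snn(emb, k = min(20, ncol(norm) - 1), seed = config$seed)
    mk <- rank_markers(norm, cl$labels)
    sets <- specific_gene_sets(mk)
    per_cohort[[co]] <- list(cells = sc$meta$cell_id[idx], norm = norm,
                             embedding = emb, labels = cl$labels,
                             markers = mk, sets = sets, n_pcs = npc)
    utils::write.csv(data.frame(cell_id = sc$meta$cell_id[idx],
                                cluster = cl$labels),
                     file.path(out_dir, paste0("clusters_", co, ".csv")),
                     row.names = FALSE)
    utils::write.csv(mk, file.path(out_dir, paste0("markers_", co, ".csv")),
                     row.names = FALSE)
  }

  ref <- per_cohort[[cohorts[1]]]
  sim_mat <- NULL
  if (length(cohorts) >= 2) {
    other <- per_cohort[[cohorts[2]]]
    if (length(ref$sets) && length(other$sets)) {
      sim_mat <- cross_cohort_matrix(ref$sets, other$sets)
      utils::write.csv(sim_mat, file.path(out_dir, "similarity.csv"))
      utils::write.csv(top_pairs(sim_mat, k = 3),
                       file.path(out_dir, "top_pairs.csv"), row.names = FALSE)
    }
  }

  tree <- fit_principal_tree(ref$embedding, ref$labels)
  if (is.null(root_cluster)) {
    deg <- tabulate(c(tree$edges$from, tree$edges$to),
                    nbins = nrow(tree$node_coords))
    leaves <- which(deg == 1)
    root_cluster <- rownames(tree$node_coords)[min(leaves)]
  }
  tree <- root_and_time(tree, root_cluster)
  cmp <- cluster_mean_pseudotime(tree$pseudotime, ref$labels)
  utils::write.csv(data.frame(cell_id = ref$cells,
                              pseudotime = tree$pseudotime,
                              state = tree$state),
                   file.path(out_dir, "pseudotime.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(nodes = rownames(tree$node_coords),
         edges = tree$edges, branch_points = tree$branch_points,
         root = tree$root, node_time = tree$node_time),
    file.path(out_dir, "tree.json"), auto_unbox = TRUE, digits = 10)

  signature <- build_signature(ref$norm, ref$labels, ref$sets)
  props_svr <- deconvolve_svr(signature, bulk$bulk)
  props_nnls <- deconvolve_nnls(signature, bulk$bulk)
  utils::write.csv(props_svr$proportions,
                   file.path(out_dir, "proportions_svr.csv"))
  utils::write.csv(props_nnls$proportions,
                   file.path(out_dir, "proportions_nnls.csv"))

  scores <- patient_pseudotime_score(props_svr, cmp)
  prog_groups <- dichotomize_by_survival(bulk$survival)
  content <- compare_cluster_content(props_svr, prog_groups)
  lr_prog <- logrank_test(bulk$survival, prog_groups)
  cut <- optimal_cutpoint(scores$score, bulk$survival, n_perm = n_perm)
  km <- km_curve(bulk$survival, cut$groups)
  utils::write.csv(data.frame(scores,
                              prognosis_group = unname(prog_groups),
                              stratum = unname(cut$groups)),
                   file.path(out_dir, "patient_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(content, file.path(out_dir, "cluster_content.csv"),
                   row.names = FALSE)
  utils::write.csv(km, file.path(out_dir, "km_curves.csv"), row.names = FALSE)

  hubs <- NULL
  key_used <- NA
  coexpr_genes <- function(cl) ref$sets[[as.character(cl)]]
  if (is.null(key_cluster)) {
    cand <- names(sort(cmp, decreasing = TRUE))
    for (cl in cand) {
      if (sum(ref$labels == as.integer(cl)) >= 10 &&
          length(coexpr_genes(cl)) >= 15) {
        key_cluster <- cl
        break
      }
    }
  }
  if (!is.null(key_cluster) && length(coexpr_genes(key_cluster)) >= 15) {
    key_used <- key_cluster
    expr <- ref$norm[coexpr_genes(key_cluster),
                     ref$labels == as.integer(key_cluster), drop = FALSE]
    net <- tryCatch(build_coexpr_network(expr), error = function(e) NULL)
    if (!is.null(net) && any(net$module != "grey")) {
      hubs <- hub_genes(net)
      utils::write.csv(data.frame(gene = names(net$module),
                                  module = unname(net$module)),
                       file.path(out_dir, "modules.csv"), row.names = FALSE)
      utils::write.table(hubs$retained_edges,
                         file.path(out_dir, "network_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  summary <- list(
    seed = config$seed,
    n_clusters = lapply(per_cohort, function(x) max(x$labels)),
    n_pcs = lapply(per_cohort, function(x) x$n_pcs),
    root_cluster = root_cluster,
    n_branch_points = length(tree$branch_points),
    n_states = max(tree$state),
    logrank_p_prognosis_groups = lr_prog$p,
    cutpoint = cut$cutpoint,
    cutpoint_statistic = cut$statistic,
    logrank_p_cutpoint = cut$p,
    logrank_p_cutpoint_permutation = cut$p_perm,
    key_cluster = key_used,
    hub_genes = if (!is.null(hubs)) hubs$hubs else character(0)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  invisible(list(sc = sc, bulk = bulk, cohorts = per_cohort,
                 similarity = sim_mat, trajectory = tree,
                 cluster_mean_pt = cmp, signature = signature,
                 proportions_svr = props_svr, proportions_nnls = props_nnls,
                 scores = scores, content = content, cutpoint = cut,
                 summary = summary))
}
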