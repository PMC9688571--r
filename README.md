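# trajscore

Linking single-cell heterogeneity to patient outcome. Glioblastoma and
other aggressive tumors contain malignant cell populations at different
developmental states; where a patient's tumor sits along that development
may carry prognostic information that cluster composition alone does not.
`trajscore` implements the full analytical chain needed to test that idea:

1. cluster single cells (SNN graph + Louvain) after log-normalization,
   mean/dispersion-bin HVG selection and PCA with elbow selection;
2. call cluster-specific marker genes (Wilcoxon rank-sum,
   `p_adj < 0.05`, `|log2FC| > 1`);
3. match clusters across cohorts by the Jaccard similarity of their
   marker sets;
4. infer a principal-tree pseudotime (cluster-centroid minimum spanning
   tree, orthogonal projection, geodesic distance from a chosen root),
   with branch points, states and per-gene expression trends;
5. deconvolve bulk expression into cluster proportions with a
   CIBERSORT-style linear ν-SVR on a marker-gene signature matrix (NNLS
   reference solver included);
6. score each patient with the **pseudotime value**

   `score_b = Σ_c w_bc · τ̄_c`

   where `w_bc` is the estimated proportion of cluster `c` in sample `b`
   and `τ̄_c` the mean pseudotime of the cluster's cells, and test its
   prognostic effect by maximally selected log-rank cutpoint
   stratification (naive and permutation-adjusted p-values);
7. rank hub genes of a key cluster in a lean weighted co-expression
   network (soft-threshold adjacency, topological overlap, static tree
   cut with grey-module removal, top-1% edge retention).

A seeded synthetic-data generator with planted ground truth (clusters on
a branching latent trajectory, marker and gradient genes, Dirichlet bulk
mixtures, exponential survival whose hazard rises with the true score)
backs every stage with recovery tests. The methods vignette
(`vignettes/trajscore-methods.Rmd`) documents the model, the defaults and
the design decisions.

## Worked example

```r
library(trajscore)

# a seeded synthetic study: 600 cells in 5 clusters on a branching
# trajectory, 100 bulk samples with survival
cfg <- sim_config(n_genes = 1500, n_cells = 600, n_clusters = 5,
                  n_patients = 100, seed = 1)
sc   <- simulate_cells(cfg)
bulk <- simulate_bulk(sc, cfg)

# single-cell side: normalize, call markers, fit the principal tree
norm <- lognormalize(filter_unexpressed(sc$counts))
markers <- rank_markers(norm, sc$truth$cell_cluster)
sets <- specific_gene_sets(markers)
lengths(sets)
#>   1   2   3   4   5
#>  67  50 103  83 103

hv  <- select_hvg_mvp(norm)
emb <- run_pca(norm, hv, n_components = 20)$embedding
tree <- root_and_time(fit_principal_tree(emb, sc$truth$cell_cluster),
                      root_cluster = 1)
tau <- cluster_mean_pseudotime(tree$pseudotime, sc$truth$cell_cluster)
round(tau, 2)
#>     1     2     3     4     5
#>  0.49 13.48 12.40 25.96 26.41

# bulk side: deconvolve, score each patient, stratify survival
sig   <- build_signature(norm, sc$truth$cell_cluster, sets)
props <- deconvolve_svr(sig, bulk$bulk)
scores <- patient_pseudotime_score(props, tau)
head(scores, 3)
#>   sample_id    score
#> 1      P001 25.07491
#> 2      P002 17.74597
#> 3      P003 13.29336

cut <- optimal_cutpoint(scores$score, bulk$survival, n_perm = 1000)
c(cutpoint = round(cut$cutpoint, 2), chisq = round(cut$chisq, 2),
  p = signif(cut$p, 3), p_perm = signif(cut$p_perm, 3))
#> cutpoint    chisq        p   p_perm
#>   6.7300   4.1900   0.0408   0.0999
```

Each cluster contributes 50 planted markers (plus genes it down-regulates
relative to others), cluster mean pseudotimes increase along the planted
trajectory (cluster 1 is the root), and splitting the cohort at the
optimal score cutpoint separates survival: the naive log-rank p at the
selected cut is 0.041, and the selection-bias-corrected permutation p is
0.10 — the example illustrates exactly why the package reports both.

The whole pipeline, including writing every intermediate artifact as
plain text, runs as one call (or via the bundled CLI wrapper):

```sh
Rscript inst/scripts/run-pipeline.R --seed 1 --out run1 --n-cells 600
```

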