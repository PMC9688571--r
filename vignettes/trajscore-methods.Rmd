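---
title: "From single-cell trajectories to patient prognosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-cell trajectories to patient prognosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscore)
```

## The analytical chain

`trajscore` implements a complete chain from single-cell RNA-seq
heterogeneity to patient-level prognosis in bulk cohorts:

1. **Preprocess** — library-size log-normalization
   (`log(1 + 10^4 · c_gc / L_c)`, natural log), removal of genes expressed
   in no cell, highly variable gene (HVG) selection by mean/dispersion
   binning, PCA on standardized HVGs with elbow-based component selection,
   and Louvain community detection on a pruned shared-nearest-neighbor
   (SNN) graph.
2. **Markers** — per cluster, a two-sided Wilcoxon rank-sum test of each
   gene against all other cells, fold changes on de-logged means with a
   pseudocount of 1, Benjamini–Hochberg adjustment within cluster, and a
   *specific* flag at `p_adj < 0.05` and `|log2FC| > 1`.
3. **Similarity** — cluster correspondence across cohorts by the Jaccard
   coefficient `|A∩B| / |A∪B|` of specific-gene sets.
4. **Trajectory** — a principal tree: cluster centroids as nodes, their
   Euclidean minimum spanning tree as edges, orthogonal projection of every
   cell onto its nearest edge. After rooting, a cell's pseudotime is the
   geodesic (along-tree) distance from the root to its projected point, and
   states are the maximal unbranched segments of the tree.
5. **Deconvolution** — a signature matrix of mean de-logged expression of
   the specific genes per cluster; per bulk sample, cluster proportions by
   linear ν-support-vector regression on standardized data (ν selected from
   {0.25, 0.5, 0.75} by reconstruction RMSE, negative coefficients clipped,
   renormalized to sum 1), with non-negative least squares as a reference
   solver.
6. **Prognosis** — the patient pseudotime value
   `score_b = Σ_c w_bc · τ̄_c`, the proportion-weighted mean cluster
   pseudotime; good/poor groups by median survival split; per-cluster
   content comparison by rank-sum tests; Kaplan–Meier curves and the
   two-group log-rank test; and survival stratification at the score
   cutpoint maximizing the standardized log-rank statistic.
7. **Co-expression** — on a key cluster's cells and specific genes: MAD
   filtering, unsigned soft-threshold adjacency `|cor|^β`, topological
   overlap (TOM), average-linkage modules under a static tree cut with
   small clusters labeled grey, retention of the top 1% of non-grey edges
   by weight, and hub ranking by retained-edge degree.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `scale_factor` | 1e4 | target library size before `log1p` |
| `n_bins`, `z_cutoff`, `mean_bounds` | 20, 1.0, (0.0125, 8) | HVG dispersion bins, within-bin z threshold, log-mean bounds |
| `k`, `resolution`, `prune` | 20, 0.8, 1/15 | SNN neighbors (self included), Louvain resolution, SNN Jaccard pruning |
| `p_adj_cutoff`, `log2fc_cutoff` | 0.05, 1 | marker-specificity thresholds |
| `nu_grid` | 0.25, 0.5, 0.75 | ν-SVR model-selection grid |
| `minprop` | 0.1 | minimum group fraction on each side of a survival cutpoint |
| `beta`, `cut_height`, `min_size` | 6, 0.25, 10 | soft-threshold power, static cut height on 1−TOM, minimum module size |
| `top_edge_fraction` | 0.01 | fraction of non-grey edges retained for hub ranking |

The HVG "mean" used for binning and bounds is the re-logged mean of the
de-logged values (`log1p(mean(expm1 x))`), so the default bounds act on a
log scale; the dispersion is the variance/mean ratio of the de-logged
values, z-scored within each equal-width mean bin. Bins with fewer than two
genes contribute no selections and raise a warning.

## What the synthetic generator emulates

`sim_config()`/`simulate_cells()`/`simulate_bulk()` produce a study with
known ground truth shaped like a two-cohort single-cell atlas plus a bulk
survival cohort:

- **Clusters on a tree.** Cluster centers sit at integer depths of a
  user-supplied tree topology (root = cluster 1, unit edges); each cell
  jitters uniformly by ±half an edge along its cluster's parent or child
  edge, and its latent time is the tree depth rescaled to [0, 1].
- **Expression.** Counts are negative binomial with shared dispersion;
  gene base abundances are log-normal. Marker genes are discrete — their
  mean is multiplied by `2^marker_log2fc` in the owning cluster only — so
  the planted fold change is exactly defined. A second set of *gradient*
  genes loads linearly on a latent embedding of the topology in which
  every tree edge has its own orthogonal axis. The orthogonal-axis
  construction makes Euclidean distance between cluster centers strictly
  monotone in tree distance, which is what lets the centroid MST recover
  the planted topology; random edge directions in a low-dimensional space
  do not have this property (two branches can fold onto each other).
- **Bulk mixtures.** Sample `b` is `Σ_c w_bc · profile(c)` over empirical
  cluster mean count profiles, plus Gaussian noise with per-gene standard
  deviation `bulk_noise_sd ×` the gene's mean profile value (so 0.1 means
  "10% of signal"). Mixing weights are symmetric Dirichlet with
  concentration 0.3: bulk tumors are typically dominated by one or a few
  subclones, and this concentration spreads the true patient scores widely
  enough that a unit log-hazard ratio per score unit is a detectable
  effect at realistic cohort sizes — a choice made from a power analysis
  at design time, not tuned afterwards.
- **Survival.** Event times are exponential with log-hazard
  `log(baseline) + score_log_hazard_ratio · score`; the default baseline
  (`log(2)/430` per day) matches a ~14-month median survival, and the
  default censoring rate (7e-4 per day, independent exponential) yields
  roughly 30% censoring.

What it does **not** emulate: doublets, batch and platform effects,
ambient RNA, gene–gene correlation beyond the planted co-expression
blocks, non-proportional hazards, and covariate structure (age, IDH
status). Passing recovery tests on this generator therefore demonstrates
that the chain is implemented correctly and has the claimed operating
characteristics *under its own assumptions*; it does not certify
performance on real atlases, where cluster boundaries are fuzzier and
signatures collinear.

The co-expression generator (`simulate_coexpr()`) plants two tight blocks
(member loading 0.985 on a shared factor, hub loading 0.998) of 150 genes
plus independent background genes. The tightness and size are forced by
the downstream rules, not by realism: a static cut at height 0.25 on
1−TOM only binds blocks whose internal TOM reaches ~0.85 (requiring
member correlations near 0.97 at β = 6), and the top-1% edge budget —
`ceiling(0.01 × C(n,2))` — must exceed the `2(g−1)` hub-incident edges for
both hubs to surface, which needs blocks of roughly 150 genes. Real WGCNA
practice uses a dynamic tree cut precisely because real modules are
looser; the static cut was chosen here for determinism and testability,
and the generator documents its cost.

## Numerical and design choices

- **Wilcoxon p-values.** Groups of at most 8 cells each are tested with
  the exact rank-sum distribution (ties fall back to the tie-corrected
  normal approximation); larger groups use the tie-corrected normal
  approximation without continuity correction, vectorized over genes.
- **Elbow-only component selection.** The number of PCs is the first `n`
  whose cumulative variance ratio reaches 0.90 or whose next component
  adds less than 0.005. Permutation-based PC testing adds cost without
  changing the downstream score, whose only trajectory inputs are per-cell
  pseudotimes and their cluster means.
- **Principal tree instead of a learned graph.** DDRTree-style latent
  trees are replaced by the centroid MST with orthogonal projection. The
  construction is deterministic, exactly testable against brute-force
  spanning-tree search, and sufficient for a score built from cluster-mean
  pseudotimes. Cells tie-break to the lower edge index when equidistant
  from two edges; a single-cluster input is rejected with advice to use a
  linear pseudotime instead.
- **Root choice.** The trajectory root is a required argument of
  `root_and_time()`; `run_pipeline()` defaults to the lowest-indexed leaf
  of the fitted tree. Orientation is a genuine degree of freedom of any
  pseudotime method; it is surfaced as configuration instead of guessed.
- **Degree-2 roots.** States are maximal unbranched segments; a root of
  degree 2 is interior to one segment, so both root edges share a state.
- **SVR standardization.** The signature matrix is standardized by its
  global mean and standard deviation and each bulk column is z-scored over
  the shared genes, making proportions invariant to positive rescaling of
  any bulk sample. Quantile normalization and the permutation p-values of
  the original bulk-deconvolution recipe are omitted: only the point
  estimates of content feed the downstream score.
- **Cutpoint selection and its bias.** Candidates are midpoints between
  consecutive distinct scores leaving at least `minprop` of samples on
  each side; each is scored by the conditional standardized log-rank
  statistic built from Nelson–Aalen log-rank scores
  (`a_i = δ_i − Λ̂(t_i)`), the form used by maximally selected rank
  statistics. The reported p-value at the chosen cut is the ordinary
  log-rank p, which is how the common survival-cutpoint tools report it —
  and it is biased low because the cut was optimized: under a true null
  this "naive" p rejects at well above the nominal level (about 30–45% at
  n = 150 with `minprop = 0.1` in our null simulations, consistent with
  the maximally-selected-statistics literature). `optimal_cutpoint()`
  therefore also offers a permutation-adjusted p (`n_perm` relabelings of
  the log-rank scores, default 1000 when enabled), which is calibrated to
  the nominal level in the same simulations. Conclusions about
  prognostic value should rest on the adjusted p.
- **Median prognosis split.** Good/poor dichotomization uses the median
  observed time, ties going to "good"; censored samples enter by their
  censoring time. This is the documented default where the original
  procedure is ambiguous. Cluster-content tests are reported with raw
  p-values (matching the single-stage convention) alongside a BH-adjusted
  column.
- **Marker FDR accounting.** A marker planted in cluster A is genuinely
  down-regulated in cluster B relative to B's background, so a
  cross-cluster "specific" call on a planted gene is a true detection.
  False-positive accounting in the validation suite therefore counts
  calls on genes with no planted effect anywhere.

## Problem sizes used in validation

The packaged validation suite runs at deliberately desk-scale sizes chosen
to give stable operating characteristics: 600 cells × 1000–1500 genes for
marker, deconvolution and trajectory recovery; 100–150 bulk samples; 100
seeded survival simulations (1000 permutation relabelings each under the
null); 50 co-expression replicates. The same quantities are recomputed
from scratch by `scripts/acceptance.R`.

## Known limitations

- The SNN/Louvain stage can split large diffuse clusters at the default
  resolution; cluster count should be read as resolution-dependent.
- The principal tree cannot represent trajectories whose branches curve
  back on themselves in expression space, and pseudotime inside a cluster
  is only as good as the local linear projection.
- Signature collinearity (rank-deficient cluster profiles) is flagged but
  not repaired; proportions for collinear clusters are unidentifiable.
- The naive cutpoint p is anti-conservative by construction (see above).
- The static TOM cut requires unusually tight modules; use a smaller
  `cut_height` or external dynamic-cut tooling for looser structure.
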