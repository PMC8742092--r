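---
title: "Discovering cell types with manifold learning: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cell types with manifold learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter and why their
defaults are what they are, the numerical choices, what the synthetic
generators do and do not emulate, and the known limitations.

## The problem and the model

Single-cell RNA-seq yields a cells × genes matrix of non-negative integer
counts, typically with thousands of genes, strong sparsity, and cell-wise
technical variation (library size, cell damage). When cell types are not
annotated, discovering them is a clustering problem — but Euclidean
distances in the raw space are dominated by technical noise and by the
curse of dimensionality, and cells of one type occupy curved regions that
linear projections fold together. The package's answer is a two-step
representation: a *locally linear* manifold embedding that preserves each
cell's neighborhood geometry, followed by a *globally linear* independent
component analysis that rotates the embedded coordinates toward
statistically independent axes, on which plain k-means then works well.

## Pre-processing

**QC filters** run in a fixed order: (1) genes expressed in fewer than
`min_cells_per_gene = 3` cells are removed (support counted over all input
cells); (2) cells expressing fewer than `min_genes_per_cell = 200` of the
surviving genes are removed — a low expressed-gene count marks dead or
degraded cells; (3) cells whose mitochondrial fraction over surviving genes
exceeds `max_mito_pct = 5`% are removed (prefix match `MT-`,
case-insensitive) — mitochondrial enrichment marks broken cells. The
first two defaults follow the standard published protocol; the protocol
reports filtering on the mitochondrial distribution without printing its
cutoff, so 5% is this package's documented, configurable choice. The order
genes → cells → mito is fixed here because the rules alone do not determine
it; a second application with the same thresholds is a no-op on typical
data.

**Normalization** is counts per million with a natural-log transform:
`CPM_ij = count_ij / totalReads_i × 10^6`, then `log(1 + CPM)`. Each
cell's CPM row sums to exactly 10^6 before the log. The log base and the
`1 +` offset are conventions (only "logarithmic scaling" is prescribed by
the protocol); the natural log keeps fold changes in natural-log units
downstream.

**Highly variable genes.** Per gene, the mean `μ_g` and the dispersion
`var_g / μ_g` are computed on the log-normalized values; genes with
`μ_g = 0` are excluded. Genes are binned by `μ_g` into `n_bins = 20`
equal-occupancy bins and the dispersions are z-scored within each bin
(population SD; a bin with a single gene uses SD 1), which removes the
mean–dispersion trend so that variability is comparable across expression
strata. Selected genes need normalized dispersion ≥ `min_disp = 0.5` and
`0.1 ≤ μ_g ≤ 12` — the mean window is expressed on the log1p-CPM scale of
this pipeline (which runs to ~13.8 at 10^6 counts-per-million) and only
excludes near-silent and saturated genes; windows quoted for pipelines
that normalize to 10^4 total counts do not transfer to this scale.

**Covariate regression and scaling.** Per gene, ordinary least squares on
an intercept, total counts, and mitochondrial percentage; values are
replaced by residuals (constant or collinear covariate columns are dropped
with a warning). Regression runs after HVG restriction — cheaper, and
consistent with running the feature selection on normalized rather than
regressed values; the alternative order is available by calling
`regress_out()` before `select_hvgs()`. Finally each gene is centered,
divided by its population SD (zero-variance genes map to 0), and clipped
to ±10 so single extreme cells cannot dominate the embedding. Population
(ddof = 0) standard deviations are used throughout the package.

## Modified locally linear embedding

For each cell `x_i`, the `t` nearest neighbors by Euclidean distance are
found exactly (no approximate search), ties broken by smaller index so the
graph is deterministic even with duplicate points. Standard LLE
reconstructs `x_i` from its neighbors with weights summing to one, solving
the regularized local Gram system
`(G_i G_i^T + tolerance · trace(G_i G_i^T)/t · I) w = 1` with
`G_i = [..., x_t − x_i, ...]`, then embeds by the bottom eigenvectors of
`(I − W)^T (I − W)` (the constant eigenvector discarded). The ridge scale
`tolerance` is the package's reading of the protocol's tolerance factor
(swept over decades 10^-12..10^-3, the observed range); it controls how
strongly near-singular local Gram matrices are stabilized, which is the
parameter standard LLE is notoriously sensitive to.

MLLE replaces the single weight vector by `s_i` vectors built from the
trailing singular directions of `G_i`: the directions are rotated by a
Householder transform so every vector still sums to one, and the
`(1 − α_i)`-weighted regularized LLE vector is added. `s_i` is the largest
`s ≤ t − m` whose trailing-to-leading squared-singular-value ratio stays
below a threshold `η`; by default `η` is the median over points of the
ratio between the residual and the leading `m`-dimensional local energy
(the original multi-weight rule), overridable via `eta_gamma`. Averaging
over a whole bundle of near-optimal weight vectors is what removes the
regularization sensitivity. Setting `single_weight = TRUE` forces one
(regularized LLE) vector per point, which reproduces standard LLE's
alignment matrix exactly — useful for equivalence tests.

Numerical choices: the alignment matrix is symmetrized and decomposed with
a dense symmetric eigen-solver — deterministic and fast at the package's
problem sizes (hundreds to a few thousand cells); eigenvector signs are
fixed so each coordinate's largest-magnitude entry is positive; `t > m` is
required (otherwise no trailing direction exists) and enforced with a
parameter error. MLLE embeddings satisfy `Y^T Y = I` and have near-zero
column means; their cost `Σ_i Σ_l ‖y_i − Σ_t w^l_ti y_t‖²` equals
`tr(Y^T M Y)`, exposed via `embedding_cost()` so optima can be compared
against feasible alternatives (e.g. an orthonormalized PCA projection).

One geometric consequence worth knowing: on data with `K` well-separated
clusters the neighbor graph decomposes, and the embedding represents each
component by (near-)indicator directions. `m` coordinates can separate at
most `m + 1` such components, so the default `m = 3` is appropriate for
K ≥ 4 — which matches the sweep's `k` grid starting at 4. For data with
very few types, reduce `dims`.

## Independent component analysis

The embedding is centered and whitened by eigen-decomposition of its
covariance (components below 10^-12 of the leading eigenvalue are
dropped), then unmixed by symmetric (parallel) FastICA with the log-cosh
contrast (a = 1), the community-default estimator for the `V = AB`
blind-source-separation model with unknown mixing `A`. Iteration stops
when every component's direction changes by less than `tol = 1e-6` or at
`max_iter = 500`, in which case the result is returned with a
`converged = FALSE` flag and a warning (on purely Gaussian input ICA is
undefined and non-convergence is expected behavior, not an error).
Components are ordered by descending non-Gaussianity (squared deviation of
the mean contrast from its Gaussian expectation) and signs are fixed so
each component's skewness is non-negative — two conventions that make
projections reproducible across runs. Clustering consumes the ICA space by
default (`cluster_space = "ica"`, the reading on which the protocol's
final figures are based); `cluster_space = "mlle"` clusters the manifold
coordinates directly, and the space used is recorded in the output.

## Clustering and validity

k-means minimizes the within-cluster sum of squared distances to
centroids. Initialization is k-means++ with `n_init = 10` restarts (pure
random initialization is available via `init = "random"` for fidelity to
the simplest textbook variant); Lloyd iterations stop when the largest
centroid displacement falls below `tol = 1e-6`; an emptied cluster is
repaired by moving the point farthest from the largest cluster's centroid
into it. The per-iteration SSE trace of every restart is stored and is
non-increasing; the best-SSE restart wins. Fixed `(seed, n_init)` gives
bit-identical assignments.

Three internal validity indices are implemented with an independent
brute-force oracle (`validity_oracle()`, plain double loops, used in
tests): Silhouette (`(b − w)/max(w, b)` averaged over cells, singleton
clusters contributing 0 by the standard convention), Calinski–Harabasz
(`tr(S_B)/tr(S_W) × (n − k)/(k − 1)`; a zero within-dispersion returns
`Inf` with a warning), and Davies–Bouldin (mean over clusters of the worst
`(w_i + w_j)/d_ij`; coincident centroids are an error naming the pair).
The between-cluster term of the Silhouette is the minimum over other
clusters of the mean distance to that cluster's members.

## Parameter selection

`sweep_grid()` embeds once per `(t, m, tolerance)` — all `k` records of a
configuration share the identical embedding — clusters for every `k`, and
scores all three indices in the clustering space. Default grids are
`t = 8..24` and `k = 4..14` (the published ranges; 187 cells per
`(m, tolerance)` pair), `m = 3` (the final reduction used for
visualization and clustering; per-dataset values up to 7 can be supplied
via `m_grid`), and tolerance decades 10^-12..10^-3. For datasets that
benefit from an intermediate reduction, `dims_stage1` in the pipeline
configuration runs MLLE twice — first to 5–7 dimensions, then down to the
final `dims` — before ICA and clustering. Infeasible cells
(`t ≤ m`) and degenerate ones (e.g. coincident centroids at large `k` on a
collapsed embedding) are logged, not fatal. Selection is `sh_primary`:
maximize Silhouette, ties broken by higher CH, lower DB, smaller `k`,
smaller `t` — Silhouette judges the clustering, CH and DB verify it; a
`rank_sum` rule over all three indices is available. `elbow_select()`
automates the elbow read-off as the `k` of maximal perpendicular distance
from the chord joining the first and last `(k, score)` points, flagging
exactly collinear profiles as having no elbow.

## Marker genes

For each cluster, a two-sided one-vs-rest Wilcoxon rank-sum test per gene,
using the normal approximation with tie correction (ranks computed once
per gene across all cells); Benjamini–Hochberg adjustment across genes
within each cluster; rows sorted by ascending p, then descending |z|, then
gene name, keeping the top 20 by default. Markers are computed on
log-normalized (not regressed, not scaled) values so the reported
`log_fold_change = mean(in) − mean(out)` stays in interpretable
natural-log units; the z statistic itself is rank-based and invariant to
any monotone transform. Exports: `.rnk` (gene, signed z, descending) and
`.grp` per cluster, the plain-text formats consumed by standard
enrichment tools. Cluster annotation itself (gene-set enrichment, GO
networks) is deliberately out of scope beyond these exports.

## Synthetic data: what it emulates, and what it does not

`make_nb_counts()` draws baseline gene means log-normal(0, 1), plants
differential expression in a `de_frac = 0.1` fraction of non-mitochondrial
genes per cluster at `lfc = 2` natural-log units (signs split ± so library
size does not confound cluster identity; `de_sign = "up"` and
`de_clusters` allow planting markers in one cluster only), and draws
counts negative-binomial with dispersion 0.5 — moderate scRNA-seq
overdispersion — scaled by per-cell library factors uniform in
[0.5, 2]. 2% of genes carry the `MT-` prefix. Labels are balanced. This
emulates overdispersed counts, library-size variation, and a labeled
mitochondrial subset; it does **not** emulate zero inflation beyond the
negative binomial, batch effects, doublets, ambient RNA, or the empirical
mean–variance shapes of any particular protocol — so green tests support
the method's logic, not its performance on any real accession.

`make_swiss_roll()` is the classical rolled surface
`(t cos t, h, t sin t)`, `t ∈ [1.5π, 4.5π]`, with Gaussian noise
(default SD 0.05). The height defaults to 10 so that a few hundred points
sample the surface densely enough for local linearity at neighborhood
sizes around 10; much taller rolls at the same `n` are under-sampled and
cap the trustworthiness of *any* local method well below what the surface
itself allows.

`make_nonlinear_blobs()` plants `K` unit-variance Gaussian blobs in R³
with centers rejection-sampled in a ball so the minimum pairwise distance
equals `separation` (default 6σ), then lifts to R^d through a fixed smooth
map: a near-isometric linear backbone plus sinusoidal and quadratic
bending, plus small ambient noise. The backbone is deliberate: it
preserves the latent cluster gaps, which at 6σ with hundreds of points per
blob are already *marginal* for a 12-NN graph — Gaussian tails place a few
cross-cluster neighbor pairs in most draws. That marginality is realistic
(real cell types touch), and it is why the pipeline's parameter
optimization matters: the MLLE-versus-PCA comparison is run by selecting
`(t, m)` per dataset by best Silhouette, exactly as the full protocol
selects its parameters. Note also that `separation = 0` does **not** drive
the Silhouette to zero: k-means optimizes compactness, and any Voronoi
partition of a single blob scores around 1/3 — the structureless baseline
to compare against is ~0.33, not 0.

`make_mixed_sources()` mixes two independent uniform sources by the fixed
matrix `A = [[2, 1], [1, 1]]` — the standard blind-source-separation
fixture.

## Problem sizes and determinism

The shipped tests and the acceptance script run at `n` up to 1,000 cells ×
2,000 genes for the end-to-end pipeline, 800 points for the swiss roll,
and 5,000 samples for source separation — sizes the package's dense
solvers handle in seconds and that are large enough for the stochastic
contracts (ARI, trustworthiness, recovery correlations) to be stable
across seeds. Every stochastic routine takes an explicit integer seed;
sweeps derive per-configuration seeds deterministically from the base
seed, and rerunning any pipeline with the same configuration and seed
reproduces byte-identical artifacts.

## Known limitations

- MLLE requires a connected enough neighbor graph; on data whose types are
  separated by many σ the embedding represents components by indicator
  directions and `m` must be at least the number of types minus one.
- The tolerance is interpreted as the local Gram ridge scale; the
  protocol's phrase about neighbor-graph "sparsity" has no operational
  definition, and no alternative reading is implemented.
- Scores are computed in the clustering space (ICA by default). Scoring in
  the MLLE space instead can change the selected parameters; both
  routings are supported and the choice is recorded.
- No batch integration, doublet detection, or ambient-RNA correction; no
  t-SNE/Isomap/Laplacian-eigenmap/UMAP/DBSCAN re-implementations — PCA and
  standard LLE are the only internal baselines.
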