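# scmanifold

Unsupervised cell-type discovery for single-cell RNA-seq. Given a cells ×
genes count matrix with no annotation, `scmanifold` finds compact,
well-separated groups of cells and the marker genes that define them, by
combining nonlinear manifold learning with independent component analysis
and k-means clustering.

scRNA-seq matrices are sparse and extremely high-dimensional, so cells of
the same type are close only through curved, non-metric relationships that
defeat linear projections. The pipeline therefore:

1. **QC-filters** counts — genes expressed in < 3 cells, cells expressing
   < 200 genes, and cells with > 5% mitochondrial counts are removed;
2. **normalizes** to counts per million, `CPM = count / totalReads × 10^6`,
   followed by `log(1 + CPM)`;
3. selects **highly variable genes** by binned, z-scored dispersion
   (variance/mean), regresses out total counts and mitochondrial
   percentage, and scales genes to unit variance (clipped at ±10);
4. embeds cells by **modified locally linear embedding (MLLE)**: each cell
   `x_i` is reconstructed from its `t` nearest neighbors with weights
   summing to one, `min ‖x_i − Σ_t w_ti x_t‖ s.t. Σ_t w_ti = 1`, and the
   low-dimensional coordinates `Y` minimize
   `Σ_i Σ_{l=1..s_i} ‖y_i − Σ_t w_ti^l y_t‖²` under `Y^T Y = I`, where the
   `s_i` weight vectors per neighborhood come from the trailing singular
   directions of the local difference matrix (standard LLE and PCA are
   available as baselines);
5. post-projects the embedding with **FastICA** (`V = AB`, log-cosh
   contrast, symmetric decorrelation) for enhanced separation;
6. clusters with **k-means** (k-means++ seeding, 10 restarts) minimizing
   the within-cluster sum of squares;
7. scores clusterings with **Silhouette**, **Calinski–Harabasz**, and
   **Davies–Bouldin** indices, and selects `(t, dims, tolerance, k)` by an
   exhaustive grid sweep (`t ∈ 8..24`, `k ∈ 4..14`) with a Silhouette-first
   rule plus an automated elbow criterion;
8. ranks per-cluster **marker genes** by one-vs-rest Wilcoxon rank-sum
   tests (normal approximation with tie correction, Benjamini–Hochberg
   adjusted) and exports `.rnk`/`.grp` lists for enrichment tools.

Negative-binomial count simulators with planted cell types, a swiss-roll
generator, nonlinearly embedded Gaussian blobs, and a mixed-sources fixture
give every stage a testable input with known ground truth.

## Worked example

Simulate 1,000 cells in five planted types (10% of genes shifted ±2
log-units per type), then run the full pipeline with a parameter sweep:

```r
library(scmanifold)

sim <- make_nb_counts(K = 5, n_cells = 1000, n_genes = 2000,
                      lfc = 2, de_frac = 0.1, seed = 1)
sim$counts
#> CountMatrix: 1000 cells x 2000 genes, 1169314 non-zero entries, total count 5,436,327

cfg <- default_config()
cfg$seed <- 1L
cfg$t_grid <- c(8L, 12L, 16L)   # subset of the full 8..24 grid
cfg$k_grid <- 4:10
cfg$tol_grid <- 1e-6
run <- run_pipeline(sim$counts, cfg)

run$sweep$chosen
#>    t m tolerance k sh           ch           db          sse      seed
#> 9 12 3     1e-06 5  1 4.521087e+31 3.685959e-15 1.100399e-26 125444885
```

The sweep selects `k = 5` — the planted number of cell types — at `t = 12`
neighbors. A Silhouette of 1 (and a near-zero Davies–Bouldin) means each
discovered cluster collapses to a tight, isolated group in the ICA-projected
MLLE space; the labels match the planted types exactly:

```r
mclust::adjustedRandIndex(run$summary$labels, sim$truth$labels)
#> [1] 1

head(run$markers[, c("cluster", "gene_name", "z_statistic", "adjusted_p",
                     "log_fold_change")], 3)
#>   cluster gene_name z_statistic   adjusted_p log_fold_change
#> 1       1      G832    20.43597 2.682747e-90        3.201573
#> 2       1     G1887    20.42598 2.682747e-90        4.469754
#> 3       1     G1755    20.19722 1.884714e-88        3.223135
```

The top markers of cluster 1 are genes up-shifted in that planted type
(positive z and 3–4.5 log-unit fold changes, vanishing adjusted p).

A thin command-line front end over the same functions is installed at
`inst/cli/scmanifold.R` with subcommands `simulate`, `qc`, `embed`, `ica`,
`cluster`, `score`, `sweep`, `markers`, and `run`.

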