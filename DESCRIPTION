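Package: scmanifold
Title: Cell Type Discovery in Single-Cell RNA-Seq by Manifold Learning and
    Independent Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering cell types in single-cell RNA-seq count
    matrices without prior annotation. Counts are quality-filtered, normalized to
    counts per million with log scaling, reduced to highly variable genes, adjusted
    for per-cell covariates and scaled to unit variance; cells are then embedded by
    modified locally linear embedding (with standard locally linear embedding and
    principal component analysis as baselines), optionally post-projected by
    FastICA for enhanced separation, and clustered by k-means. Cluster quality is
    scored with the Silhouette, Calinski-Harabasz and Davies-Bouldin indices;
    neighborhood size, embedding dimension, regularization tolerance and cluster
    number are chosen by an exhaustive grid sweep with an automated elbow rule.
    Per-cluster marker genes are ranked by one-vs-rest Wilcoxon rank-sum tests
    with Benjamini-Hochberg adjustment and exported for external enrichment tools.
    Negative-binomial and manifold simulators with planted ground truth support
    testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
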