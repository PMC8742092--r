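test_that("QC applies its three filters in the documented order", {
  res <- qc_filter(qc_example_counts(), min_cells_per_gene = 2L,
                   min_genes_per_cell = 2L, max_mito_pct = Inf)
  # genes g4 (support 0) and g5 (support 1) drop first, then cell r2
  # expresses a single surviving gene and drops
  expect_equal(dim(res$counts), c(3L, 3L))
  expect_equal(res$counts$gene_names, c("g1", "g2", "g3"))
  expect_equal(res$counts$cell_ids, c("r1", "r3", "r4"))
  expect_equal(res$report$n_genes_dropped_support, 2L)
  expect_equal(res$report$n_cells_dropped_genes, 1L)
})

test_that("the default QC thresholds match the published protocol", {
  fm <- formals(qc_filter)
  expect_equal(eval(fm$min_cells_per_gene), 3L)
  expect_equal(eval(fm$min_genes_per_cell), 200L)
})

test_that("mitochondrial filtering removes high-mito cells case-insensitively", {
  vals <- rbind(c(90, 5, 5),    # 90% mito
                c(2, 49, 49),
                c(1, 50, 49))
  colnames(vals) <- c("mt-ND1", "gA", "gB")
  rownames(vals) <- paste0("c", 1:3)
  res <- qc_filter(count_matrix(vals), min_cells_per_gene = 1L,
                   min_genes_per_cell = 1L, max_mito_pct = 5)
  expect_equal(res$counts$cell_ids, c("c2", "c3"))
  expect_equal(res$report$n_cells_dropped_mito, 1L)
})

test_that("QC of a fully empty matrix is an explicit error", {
  z <- count_matrix(matrix(0, 3, 3), paste0("c", 1:3), paste0("g", 1:3))
  expect_error(qc_filter(z), "empty after QC")
})

test_that("QC is idempotent and never grows the matrix", {
  sim <- make_nb_counts(K = 3, n_cells = 300, n_genes = 800, seed = 404)
  r1 <- qc_filter(sim$counts)
  r2 <- qc_filter(r1$counts)
  expect_equal(as.matrix(r2$counts$values), as.matrix(r1$counts$values))
  expect_lte(r1$report$n_cells_out, r1$report$n_cells_in)
  expect_lte(r1$report$n_genes_out, r1$report$n_genes_in)
})

test_that("CPM normalization matches its definition and sums to one million", {
  m <- count_matrix(rbind(c(30, 70), c(0, 4)), c("c1", "c2"), c("g1", "g2"))
  e <- cpm_lognormalize(m)
  expect_equal(e$stage, "normalized")
  expect_equal(e$values[1, ], log1p(c(3e5, 7e5)), ignore_attr = TRUE)
  # a single expressed gene takes the whole million
  expect_equal(e$values[2, 2], log1p(1e6))

  big <- random_counts(30, 50, seed = 11)
  keep <- Matrix::rowSums(big$values) > 0
  big <- count_matrix(big$values[keep, ], big$cell_ids[keep],
                      big$gene_names)
  cpm <- expm1(cpm_lognormalize(big)$values)
  expect_true(all(abs(rowSums(cpm) - 1e6) <= 1e-6 * 1e6))
})

test_that("CPM normalization commutes with cell permutation", {
  m <- random_counts(12, 20, seed = 21, max_count = 9)
  vals <- as.matrix(m$values) + 1L   # ensure positive totals
  m <- count_matrix(vals, m$cell_ids, m$gene_names)
  set.seed(1); perm <- sample(12)
  mp <- count_matrix(vals[perm, ], m$cell_ids[perm], m$gene_names)
  expect_equal(cpm_lognormalize(mp)$values,
               cpm_lognormalize(m)$values[perm, ])
})

test_that("zero-total cells are rejected by normalization", {
  m <- count_matrix(rbind(c(1, 2), c(0, 0)), c("a", "b"), c("g1", "g2"))
  expect_error(cpm_lognormalize(m), "qc_filter")
})

test_that("HVG selection finds over-dispersed genes and ignores flat ones", {
  set.seed(33)
  n <- 80; G <- 50
  base <- matrix(rnorm(n * G, mean = 5, sd = 0.3), n, G)
  base[, 1] <- 5 + rnorm(n, sd = 3)        # inflated dispersion in-bin
  base[, 2] <- 5                            # constant: dispersion zero
  base <- abs(base)
  e <- expression_matrix(base, paste0("c", 1:n), paste0("g", 1:G),
                         stage = "normalized")
  hv <- select_hvgs(e, n_bins = 5, min_disp = 0.5, min_mean = 0,
                    max_mean = Inf)
  expect_true(hv$hvg_mask["g1"])
  expect_false(hv$hvg_mask["g2"])
})

test_that("HVG selection is invariant to gene column order", {
  set.seed(44)
  X <- matrix(abs(rnorm(60 * 40, 4)), 60, 40)
  e <- expression_matrix(X, paste0("c", 1:60), paste0("g", 1:40),
                         stage = "normalized")
  hv <- select_hvgs(e, n_bins = 4, min_disp = 0.3, min_mean = 0,
                    max_mean = Inf)
  perm <- sample(40)
  ep <- expression_matrix(X[, perm], e$cell_ids, e$gene_names[perm],
                          stage = "normalized")
  hvp <- select_hvgs(ep, n_bins = 4, min_disp = 0.3, min_mean = 0,
                     max_mean = Inf)
  expect_equal(hvp$hvg_mask[e$gene_names], hv$hvg_mask[e$gene_names])
})

test_that("covariate regression leaves residuals orthogonal to covariates", {
  set.seed(55)
  n <- 40
  cov1 <- runif(n, 100, 1000)
  cov2 <- runif(n, 0, 10)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 1] <- 2 * cov1 + 1                    # perfectly explained gene
  e <- expression_matrix(X, paste0("c", 1:n), paste0("g", 1:10),
                         stage = "hvg")
  r <- regress_out(e, cbind(cov1, cov2))
  expect_equal(r$stage, "regressed")
  expect_true(all(abs(r$values[, 1]) <= 1e-8))
  for (g in 1:10) {
    expect_lte(abs(sum(r$values[, g] * cov1)), 1e-6)
    expect_lte(abs(sum(r$values[, g] * cov2)), 1e-6)
  }
})

test_that("all-zero covariates reduce regression to centering", {
  set.seed(56)
  X <- matrix(rnorm(30 * 5), 30, 5)
  e <- expression_matrix(X, paste0("c", 1:30), paste0("g", 1:5),
                         stage = "hvg")
  expect_warning(r <- regress_out(e, matrix(0, 30, 2)), "redundant")
  expect_equal(r$values, sweep(X, 2, colMeans(X)), ignore_attr = TRUE)
})

test_that("unit-variance scaling matches the population z-score", {
  e <- expression_matrix(cbind(g1 = c(1, 2, 3), g2 = c(7, 7, 7)),
                         paste0("c", 1:3), c("g1", "g2"),
                         stage = "regressed")
  s <- scale_unit_variance(e)
  expect_equal(s$values[, 1], c(-1.2247, 0, 1.2247),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(s$values[, 2], c(0, 0, 0), ignore_attr = TRUE)

  set.seed(66)
  X <- matrix(rnorm(50 * 8, sd = 3), 50, 8)
  e2 <- expression_matrix(X, paste0("c", 1:50), paste0("g", 1:8),
                          stage = "regressed")
  s2 <- scale_unit_variance(e2, clip_max = 100)   # no clipping active
  v <- apply(s2$values, 2, function(x) mean(x^2) - mean(x)^2)
  expect_true(all(abs(v - 1) <= 1e-9))
  # clipping bounds respected at the default
  s3 <- scale_unit_variance(e2)
  expect_true(all(abs(s3$values) <= 10))
})

test_that("stage tags enforce the pipeline order", {
  e <- expression_matrix(matrix(1.0 * 1:6, 3, 2), paste0("c", 1:3),
                         c("g1", "g2"), stage = "scaled")
  expect_error(select_hvgs(e), "stage")
  expect_error(scale_unit_variance(e), "stage")
})
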