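# small programmatic fixtures shared across test files

# integer count matrix with reproducible random entries
random_counts <- function(n_cells, n_genes, seed, max_count = 20L) {
  set.seed(seed)
  vals <- matrix(sample.int(max_count + 1L, n_cells * n_genes,
                            replace = TRUE) - 1L,
                 n_cells, n_genes)
  count_matrix(vals,
               cell_ids = paste0("c", seq_len(n_cells)),
               gene_names = paste0("g", seq_len(n_genes)))
}

# the 4-cell x 5-gene QC worked example
qc_example_counts <- function() {
  vals <- rbind(r1 = c(5, 3, 0, 0, 1),
                r2 = c(2, 0, 0, 0, 0),
                r3 = c(0, 4, 2, 0, 0),
                r4 = c(1, 1, 3, 0, 0))
  colnames(vals) <- paste0("g", 1:5)
  count_matrix(vals)
}

# points and labels for a random small clustering instance
random_instance <- function(seed, n_max = 60L, k_max = 6L, d_max = 4L) {
  set.seed(seed)
  k <- sample(2:k_max, 1L)
  n <- sample(seq(k * 2L, n_max), 1L)
  d <- sample(1:d_max, 1L)
  X <- matrix(rnorm(n * d), n, d)
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  list(X = X, labels = labels, n = n, k = k)
}
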