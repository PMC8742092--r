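#' Simulate negative-binomial scRNA-seq counts with planted cell types
#'
#' Baseline gene means are drawn log-normal (meanlog 0, sdlog 1); for each
#' of the `K` planted clusters a `de_frac` fraction of the non-mitochondrial
#' genes is shifted by `lfc` natural-log units (sign drawn half up / half
#' down under `de_sign = "both"`, so library size does not confound cluster
#' identity). Counts are negative binomial with dispersion `nb_dispersion`
#' (size = 1/dispersion), scaled by per-cell library-size factors drawn
#' uniformly from `lib_size_range`. A `mito_frac` fraction of genes is named
#' with the prefix `MT-`. Cluster labels are balanced (`n_cells/K`, +/- 1).
#' Everything is bit-reproducible from `seed`.
#'
#' @param K number of planted cell types (>= 1).
#' @param n_cells,n_genes matrix dimensions (`n_cells >= K`).
#' @param de_frac fraction of genes differentially expressed per cluster
#'   (default 0.1).
#' @param lfc natural-log fold change of DE genes (default 2).
#' @param nb_dispersion negative-binomial dispersion (default 0.5,
#'   moderate scRNA-seq overdispersion).
#' @param lib_size_range range of uniform library-size factors
#'   (default `c(0.5, 2)`).
#' @param mito_frac fraction of genes labeled mitochondrial (default 0.02).
#' @param seed integer seed.
#' @param de_sign `"both"` (default) for symmetric +/- shifts, `"up"` for
#'   up-shifts only.
#' @param de_clusters clusters that receive differential expression
#'   (default all); restricting to one cluster plants markers unique to it.
#' @return A list with `counts` (a [count_matrix()]) and `truth`
#'   (`SyntheticTruth`: `labels`, `de_mask` K x n_genes logical, `gene_mean`
#'   K x n_genes expected NB means at library factor 1, `lib_factor`,
#'   `params`).
#' @export
make_nb_counts <- function(K, n_cells, n_genes, de_frac = 0.1, lfc = 2.0,
                           nb_dispersion = 0.5, lib_size_range = c(0.5, 2.0),
                           mito_frac = 0.02, seed = 0L,
                           de_sign = c("both", "up"),
                           de_clusters = seq_len(K)) {
  de_sign <- match.arg(de_sign)
  if (K < 1L) stop("parameter error: K must be >= 1")
  if (n_cells < K) stop("parameter error: n_cells must be >= K")
  if (de_frac < 0 || de_frac > 1) {
    stop("parameter error: de_frac must lie in [0, 1]")
  }
  set.seed(as.integer(seed))

  n_mito <- round(mito_frac * n_genes)
  gene_names <- c(paste0("G", seq_len(n_genes - n_mito)),
                  if (n_mito > 0) paste0("MT-", seq_len(n_mito)))
  base_mean <- rlnorm(n_genes, meanlog = 0, sdlog = 1)

  labels <- rep(seq_len(K), length.out = n_cells)
  n_de <- round(de_frac * n_genes)
  de_mask <- matrix(FALSE, K, n_genes)
  log_shift <- matrix(0, K, n_genes)
  non_mito <- seq_len(n_genes - n_mito)
  for (kk in intersect(seq_len(K), de_clusters)) {
    de <- sample(non_mito, min(n_de, length(non_mito)))
    de_mask[kk, de] <- TRUE
    sgn <- if (de_sign == "up") rep(1, length(de)) else
      sample(c(-1, 1), length(de), replace = TRUE)
    log_shift[kk, de] <- sgn * lfc
  }
  gene_mean <- exp(sweep(log_shift, 2L, log(base_mean), "+"))  # K x G

  lib <- runif(n_cells, lib_size_range[1L], lib_size_range[2L])
  counts <- matrix(0L, n_cells, n_genes)
  size <- 1 / nb_dispersion
  for (i in seq_len(n_cells)) {
    counts[i, ] <- rnbinom(n_genes, mu = gene_mean[labels[i], ] * lib[i],
                           size = size)
  }
  cm <- count_matrix(Matrix(counts, sparse = TRUE),
                     cell_ids = paste0("cell", seq_len(n_cells)),
                     gene_names = gene_names)
  truth <- structure(list(
    labels = labels, de_mask = de_mask, gene_mean = gene_mean,
    lib_factor = lib,
    params = list(K = K, n_cells = n_cells, n_genes = n_genes,
                  de_frac = de_frac, lfc = lfc,
                  nb_dispersion = nb_dispersion,
                  lib_size_range = lib_size_range, mito_frac = mito_frac,
                  seed = as.integer(seed), de_sign = de_sign,
                  de_clusters = de_clusters)
  ), class = "SyntheticTruth")
  list(counts = cm, truth = truth)
}

#' Simulate a swiss-roll manifold
#'
#' Classical two-dimensional surface rolled up in R^3:
#' `(t cos t, h, t sin t)` with `t = 1.5 * pi * (1 + 2u)`, `u, v ~ U(0,1)`,
#' `h = height * v`, plus isotropic Gaussian noise. The default height of 10
#' keeps the surface densely sampled at a few hundred points, so
#' neighborhoods of size ~10 stay locally linear. The intrinsic coordinates
#' `(t, h)` are returned as ground truth for judging manifold recovery.
#'
#' @param n number of points (>= 10).
#' @param noise Gaussian noise standard deviation (default 0.05).
#' @param seed integer seed.
#' @param height extent of the roll's straight axis (default 10).
#' @return A list with `points` (n x 3) and `intrinsic` (n x 2).
#' @export
make_swiss_roll <- function(n, noise = 0.05, seed = 0L, height = 10) {
  if (n < 10L) stop("parameter error: n must be >= 10")
  set.seed(as.integer(seed))
  tt <- 1.5 * pi * (1 + 2 * runif(n))
  h <- height * runif(n)
  pts <- cbind(tt * cos(tt), h, tt * sin(tt)) +
    noise * matrix(rnorm(3 * n), n, 3)
  list(points = pts, intrinsic = cbind(tt, h))
}

#' Simulate nonlinearly embedded Gaussian blobs
#'
#' `K` isotropic unit-variance Gaussian blobs in R^3 with centers scaled so
#' the minimum pairwise center distance is `separation` (in units of the
#' blob sigma), lifted to R^d by a fixed smooth nonlinear map mixing
#' sinusoidal and linear-plus-quadratic coordinates, plus small Gaussian
#' noise. The sinusoid frequencies fold distant regions of the latent space
#' together, so globally linear projections mix the clusters while locally
#' linear methods keep them apart.
#'
#' @param K number of blobs (>= 2).
#' @param n number of points.
#' @param d ambient dimension (>= 4, default 50).
#' @param separation minimum center distance in sigma units (default 6; 0
#'   collapses all blobs onto one).
#' @param seed integer seed.
#' @return A list with `X` (n x d), `labels` (balanced), and `latent`
#'   (n x 3).
#' @export
make_nonlinear_blobs <- function(K, n, d = 50L, separation = 6.0, seed = 0L) {
  if (K < 2L) stop("parameter error: K must be >= 2")
  if (d < 4L) stop("parameter error: d must be >= 4")
  set.seed(as.integer(seed))
  # centers rejection-sampled in a ball of radius 1.5*separation so the
  # minimum pairwise distance is >= separation while the spread stays
  # bounded (keeps the lift below one sinusoid period across the domain)
  centers <- matrix(0, K, 3)
  if (separation > 0) {
    repeat {
      cand <- matrix(rnorm(3 * K), K, 3)
      cand <- cand / sqrt(rowSums(cand^2)) *
        (1.5 * separation * runif(K)^(1 / 3))
      dc <- as.matrix(dist(cand))
      if (min(dc[upper.tri(dc)]) >= separation) { centers <- cand; break }
    }
  }
  labels <- rep(seq_len(K), length.out = n)
  Z <- centers[labels, , drop = FALSE] + matrix(rnorm(3 * n), n, 3)

  # fixed smooth lift: a near-isometric linear backbone keeps the latent
  # cluster gaps intact while sinusoidal bending and a quadratic term curve
  # the manifold through the ambient space
  A <- matrix(rnorm(3 * d, sd = 0.15), 3, d)
  phi <- runif(d, 0, 2 * pi)
  B <- matrix(rnorm(3 * d, sd = 0.3), 3, d)
  X <- sin(sweep(Z %*% A, 2L, phi, "+")) + Z %*% B + 0.05 * (Z %*% B)^2
  X <- X + 0.05 * matrix(rnorm(n * d), n, d)
  list(X = X, labels = labels, latent = Z)
}

#' Simulate mixed independent sources for blind source separation
#'
#' Two independent zero-mean, unit-variance uniform sources mixed by the
#' fixed matrix `A = [[2, 1], [1, 1]]`; the observed signals are exactly
#' `A %*% sources`.
#'
#' @param n number of samples (>= 100).
#' @param seed integer seed.
#' @return A list with `observed` (2 x n), `sources` (2 x n), and `A`.
#' @export
make_mixed_sources <- function(n, seed = 0L) {
  if (n < 100L) stop("parameter error: n must be >= 100")
  set.seed(as.integer(seed))
  s <- rbind(runif(n, -sqrt(3), sqrt(3)), runif(n, -sqrt(3), sqrt(3)))
  A <- matrix(c(2, 1, 1, 1), 2, 2, byrow = TRUE)
  list(observed = A %*% s, sources = s, A = A)
}
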