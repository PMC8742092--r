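#' FastICA projection of an embedding
#'
#' Blind source separation of the embedding coordinates under the linear
#' mixing model `V = A B` with unknown mixing matrix `A` and statistically
#' independent latent components `B`. The data are centered and whitened by
#' eigen-decomposition of their covariance, then unmixed by the symmetric
#' (parallel) fixed-point iteration with the log-cosh contrast (a = 1).
#' Recovered components are mutually uncorrelated with unit variance;
#' components are ordered by descending non-Gaussianity (squared deviation
#' of the mean log-cosh contrast from its Gaussian expectation) and the
#' sign of each is fixed so its skewness is non-negative, making projections
#' reproducible.
#'
#' @param e an `Embedding` (method `"mlle"`, `"lle"`, or `"pca"`) or a plain
#'   n x m coordinate matrix.
#' @param n_components number of components to extract (default 2); must not
#'   exceed the embedding dimension (nor its numerical rank).
#' @param seed integer seed for the random initial unmixing matrix.
#' @param max_iter maximum fixed-point iterations (default 500).
#' @param tol convergence tolerance on the per-component direction change
#'   (default 1e-6).
#' @return A list with `embedding` (an `Embedding`, method `"ica"`, n x
#'   n_components) and `model` (`ICAModel`: whitening matrix `K`, unmixing
#'   `W`, mixing `A`, `center`, `converged`, `n_iter`, `seed`).
#' @export
fastica <- function(e, n_components = 2L, seed = 0L, max_iter = 500L,
                    tol = 1e-6) {
  Y <- .as_coords(e)                    # n x m
  n <- nrow(Y); mdim <- ncol(Y)
  nc <- as.integer(n_components)
  if (nc < 1L || nc > mdim) {
    stop(sprintf("parameter error: need 1 <= n_components <= %d", mdim))
  }
  V <- t(Y)                             # m x n, components x samples
  ctr <- rowMeans(V)
  Vc <- V - ctr

  # whitening: eigen-decomposition of the (population) covariance
  cov <- tcrossprod(Vc) / n
  eg <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-12 * max(eg$values)
  if (sum(keep) < nc) {
    stop(sprintf("parameter error: embedding has numerical rank %d < %d",
                 sum(keep), nc))
  }
  K <- t(eg$vectors[, keep, drop = FALSE]) / sqrt(eg$values[keep]) # r x m
  K <- K[seq_len(nc), , drop = FALSE]
  Z <- K %*% Vc                          # nc x n, cov(Z) = I

  set.seed(as.integer(seed))
  W <- matrix(rnorm(nc * nc), nc, nc)
  W <- .sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(as.integer(max_iter))) {
    WZ <- W %*% Z
    gwz <- tanh(WZ)
    gprime <- rowMeans(1 - gwz^2)
    W1 <- gwz %*% t(Z) / n - gprime * W
    W1 <- .sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("FastICA did not converge in %d iterations", max_iter))
  }

  S <- W %*% Z                           # nc x n independent components
  # order by descending non-Gaussianity of the log-cosh contrast
  gauss_ref <- 0.37456694416           # E[log cosh(g)], g ~ N(0, 1)
  ng <- (rowMeans(log(cosh(S))) - gauss_ref)^2
  o <- order(ng, decreasing = TRUE)
  S <- S[o, , drop = FALSE]
  W <- W[o, , drop = FALSE]
  # fix signs so each component's skewness is non-negative
  skew <- rowMeans(S^3)
  flip <- ifelse(skew < 0, -1, 1)
  S <- flip * S
  W <- flip * W
  unmix <- W %*% K                       # nc x m
  A <- .pinv(unmix)                  # m x nc mixing matrix

  src <- if (inherits(e, "Embedding")) e$method else "matrix"
  emb <- new_embedding(t(S), method = "ica",
                       params = list(n_components = nc, seed = seed,
                                     tol = tol, max_iter = max_iter,
                                     converged = converged, source = src))
  model <- structure(list(K = K, W = W, unmixing = unmix, A = A,
                          center = ctr, converged = converged,
                          n_iter = it, seed = seed),
                     class = "ICAModel")
  list(embedding = emb, model = model)
}

# symmetric (parallel) decorrelation: W <- (W W^T)^(-1/2) W
.sym_decorrelate <- function(W) {
  s <- eigen(tcrossprod(W), symmetric = TRUE)
  (s$vectors %*% (t(s$vectors) / sqrt(pmax(s$values, 1e-300)))) %*% W
}

# Moore-Penrose pseudo-inverse (small matrices only)
.pinv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
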