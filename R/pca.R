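#' Principal component embedding
#'
#' Linear baseline: eigen-decomposition of the covariance of the centered
#' data, scores on the top `m` components. Components are ordered by
#' descending eigenvalue and the sign of each is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param X numeric matrix n x d (or container accepted by [knn_graph()]).
#' @param m number of components, `m <= min(n, d)`.
#' @return An `Embedding` with method `"pca"`; `details` carries the
#'   loadings (`components`, d x m), all population eigenvalues
#'   (`eigenvalues`), and the column `center`.
#' @export
pca_embed <- function(X, m) {
  X <- .as_coords(X)
  n <- nrow(X); d <- ncol(X)
  m <- as.integer(m)
  if (m < 1L || m > min(n, d)) {
    stop(sprintf("parameter error: need 1 <= m <= min(n, d) = %d", min(n, d)))
  }
  ctr <- colMeans(X)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    p <- which.max(abs(rot[, j]))
    if (rot[p, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(X, 2L, ctr) %*% rot
  # population eigenvalues so that their sum equals the total variance
  eig_pop <- pr$sdev^2 * (n - 1) / n
  new_embedding(scores, method = "pca", params = list(m = m),
                details = list(components = rot, eigenvalues = eig_pop,
                               center = ctr))
}
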