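#' Locally linear reconstruction weights
#'
#' For each point `x_i` with neighborhood `N_i`, solves the constrained
#' least-squares problem `min || x_i - sum_t w_ti x_t ||` subject to
#' `sum_t w_ti = 1`, by solving the regularized local Gram system
#' `(G_i G_i^T + tolerance * trace(G_i G_i^T) / t * I) w = 1` with
#' `G_i = [..., x_t - x_i, ...]` and rescaling `w` to sum to one. The
#' tolerance sets the scale of the ridge term that keeps the local Gram
#' matrix invertible when neighborhoods are low-rank.
#'
#' @param X numeric matrix n x d (or a container accepted by [knn_graph()]).
#' @param g a `NeighborGraph` consistent with `X`.
#' @param tolerance regularization scale (default 1e-3).
#' @return A `LocalWeights` list with sparse `W` (n x n, row i supported on
#'   `N_i`, rows summing to 1), the neighbor `indices`, and `tolerance`.
#' @export
lle_weights <- function(X, g, tolerance = 1e-3) {
  X <- .as_coords(X)
  stopifnot(inherits(g, "NeighborGraph"), nrow(X) == g$n)
  n <- g$n; t <- g$t
  Wv <- matrix(0, n, t)
  ones <- rep(1, t)
  for (i in seq_len(n)) {
    nbr <- g$indices[i, ]
    G <- X[nbr, , drop = FALSE] - matrix(X[i, ], t, ncol(X), byrow = TRUE)
    Gram <- tcrossprod(G)
    tr <- sum(diag(Gram))
    reg <- if (tr > 0) tolerance * tr / t else tolerance
    w <- tryCatch(solve(Gram + diag(reg, t), ones),
                  error = function(e) rep(NA_real_, t))
    if (any(!is.finite(w))) {
      stop(sprintf("weight solve failed at point %d (singular local Gram)", i))
    }
    Wv[i, ] <- w / sum(w)
  }
  W <- sparseMatrix(i = rep(seq_len(n), each = t),
                    j = as.vector(Matrix::t(g$indices)),
                    x = as.vector(Matrix::t(Wv)), dims = c(n, n))
  structure(list(W = W, indices = g$indices, t = t, n = n,
                 tolerance = tolerance),
            class = "LocalWeights")
}

#' Locally linear embedding from precomputed weights
#'
#' Minimizes the embedding cost `sum_i || y_i - sum_t w_ti y_t ||^2` under
#' the normalization `Y^T Y = I` by taking the bottom eigenvectors of
#' `M = (I - W)^T (I - W)`, discarding the constant bottom eigenvector. The
#' cost at the solution equals the sum of the retained eigenvalues.
#'
#' @param w a `LocalWeights` object.
#' @param m target dimension, `1 <= m < n - 1`.
#' @return An `Embedding` (see [new_embedding()]) with method `"lle"`,
#'   carrying the alignment matrix `M` and the retained eigenvalues in
#'   `details`.
#' @export
lle_embed <- function(w, m) {
  stopifnot(inherits(w, "LocalWeights"))
  n <- w$n
  m <- as.integer(m)
  if (m < 1L || m >= n - 1L) {
    stop(sprintf("parameter error: need 1 <= m < n - 1, got m=%d, n=%d", m, n))
  }
  IW <- Matrix::Diagonal(n) - w$W
  M <- as.matrix(Matrix::crossprod(IW))
  .embed_from_alignment(M, m, method = "lle",
                        params = list(t = w$t, m = m,
                                      tolerance = w$tolerance))
}

# bottom-eigenvector extraction shared by LLE and MLLE
.embed_from_alignment <- function(M, m, method, params, extra = list()) {
  M <- (M + t(M)) / 2
  eg <- tryCatch(eigen(M, symmetric = TRUE),
                 error = function(e) stop("eigen-solver failure: ",
                                          conditionMessage(e)))
  n <- nrow(M)
  # eigen() sorts descending; bottom eigenvector (constant) is column n
  sel <- n - seq_len(m)                 # ranks 2..m+1 from the bottom
  Y <- eg$vectors[, sel, drop = FALSE]
  evals <- eg$values[sel]
  # deterministic sign: largest-magnitude entry of each coordinate positive
  for (j in seq_len(m)) {
    p <- which.max(abs(Y[, j]))
    if (Y[p, j] < 0) Y[, j] <- -Y[, j]
  }
  new_embedding(Y, method = method, params = params,
                details = c(list(M = M, eigenvalues = evals), extra))
}

#' Construct an embedding object
#'
#' @param Y n x m coordinate matrix.
#' @param method one of `"lle"`, `"mlle"`, `"pca"`, `"ica"`.
#' @param params named list of the parameters that produced the embedding.
#' @param details method internals (alignment matrix, eigenvalues, ...).
#' @return An `Embedding` list.
#' @export
new_embedding <- function(Y, method, params = list(), details = list()) {
  structure(list(Y = as.matrix(Y), method = method, params = params,
                 details = details),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding [%s]: %d points x %d dims\n", x$method,
              nrow(x$Y), ncol(x$Y)))
  invisible(x)
}

#' Embedding cost of coordinates under an alignment matrix
#'
#' Evaluates `trace(Y^T M Y)`, the (M)LLE reconstruction cost of arbitrary
#' coordinates `Y` under the alignment matrix `M` stored in an embedding's
#' `details`. Used to compare the solver's optimum against feasible
#' alternatives.
#'
#' @param M n x n alignment matrix (or an `Embedding` whose details carry one).
#' @param Y n x m coordinate matrix.
#' @return The scalar cost.
#' @export
embedding_cost <- function(M, Y) {
  if (inherits(M, "Embedding")) M <- M$details$M
  Y <- as.matrix(Y)
  sum(Y * (M %*% Y))
}
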