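#' Modified locally linear embedding
#'
#' Standard LLE reconstructs each point from a single weight vector over its
#' `t` nearest neighbors, which makes the embedding sensitive to the
#' regularization of near-singular local Gram matrices. MLLE instead uses
#' multiple weight vectors per neighborhood, built from the trailing
#' (smallest) right singular directions of the local difference matrix
#' `G_i = [..., x_t - x_i, ...]`, and minimizes
#' `sum_i sum_{l=1..s_i} || y_i - sum_t w^l_ti y_t ||^2` under `Y^T Y = I`.
#'
#' Per point, the number of retained trailing directions `s_i` is the
#' largest `s <= t - m` whose trailing-to-leading squared-singular-value
#' ratio stays below a threshold `eta` (by default the median over points of
#' the ratio between the residual and leading `m`-dimensional local energy);
#' each weight vector combines a Householder rotation of those directions
#' with the regularized single LLE weight vector so that every `w^l` sums to
#' one. The embedding is the usual bottom-eigenvector extraction of the
#' assembled alignment matrix.
#'
#' @param X numeric matrix n x d (or container accepted by [knn_graph()]).
#' @param t number of nearest neighbors; must exceed `m`.
#' @param m target dimension.
#' @param tolerance regularization scale for the single-weight solve
#'   (default 1e-3), as in [lle_weights()].
#' @param eta_gamma trailing-ratio threshold; `NULL` (default) uses the
#'   median rule above.
#' @param single_weight if `TRUE`, force one weight vector per point (the
#'   regularized LLE vector), reproducing standard LLE's alignment matrix.
#' @return An `Embedding` with method `"mlle"`; `details` carries the
#'   alignment matrix `M`, retained `eigenvalues`, the per-point counts `s`,
#'   the per-point weight bundles `weights` (each a `t x s_i` matrix whose
#'   columns sum to 1), and the neighbor `indices`.
#' @export
mlle_embed <- function(X, t, m, tolerance = 1e-3, eta_gamma = NULL,
                       single_weight = FALSE) {
  X <- .as_coords(X)
  n <- nrow(X); d <- ncol(X)
  t <- as.integer(t); m <- as.integer(m)
  if (t <= m) {
    stop(sprintf(
      "parameter error: MLLE requires t > m (t=%d, m=%d); no trailing singular direction exists otherwise",
      t, m))
  }
  if (t >= n) stop(sprintf("parameter error: need t < n, got t=%d, n=%d", t, n))
  if (m < 1L) stop("parameter error: m must be >= 1")

  g <- knn_graph(X, t)
  ones <- rep(1, t)

  evals <- matrix(0, n, t)      # squared singular values of G_i, descending
  vecs <- vector("list", n)     # eigenvectors of G_i G_i^T (columns, desc.)
  w_reg <- matrix(0, n, t)
  for (i in seq_len(n)) {
    nbr <- g$indices[i, ]
    G <- X[nbr, , drop = FALSE] - matrix(X[i, ], t, d, byrow = TRUE)
    Gram <- tcrossprod(G)
    eg <- eigen((Gram + t(Gram)) / 2, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    evals[i, ] <- ev
    vecs[[i]] <- eg$vectors
    tr <- sum(ev)
    reg <- if (tr > 0) tolerance * tr / t else tolerance
    w <- solve(Gram + diag(reg, t), ones)
    if (any(!is.finite(w))) {
      stop(sprintf("weight solve failed at point %d (singular local Gram)", i))
    }
    w_reg[i, ] <- w / sum(w)
  }

  # eta: threshold on the trailing/leading energy ratio
  lead <- rowSums(evals[, seq_len(m), drop = FALSE])
  tail_e <- rowSums(evals) - lead
  rho <- tail_e / pmax(lead, .Machine$double.eps)
  eta <- if (is.null(eta_gamma)) median(rho) else eta_gamma

  s_all <- integer(n)
  Wlist <- vector("list", n)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (single_weight) {
      s <- 1L
      Wi <- matrix(w_reg[i, ], t, 1L)
    } else {
      ev <- evals[i, ]
      total <- sum(ev)
      csum <- cumsum(ev)
      s <- 1L
      for (cand in seq_len(t - m)) {
        head_sum <- csum[t - cand]
        ratio <- (total - head_sum) / pmax(head_sum, .Machine$double.eps)
        if (ratio < eta) s <- cand
      }
      Vi <- vecs[[i]][, (t - s + 1L):t, drop = FALSE]
      cs <- colSums(Vi)
      alpha <- sqrt(sum(cs^2) / s)
      h <- alpha - cs
      nh <- sqrt(sum(h^2))
      h <- if (nh < 1e-12) rep(0, s) else h / nh
      # Householder rotation making every column sum to alpha, plus the
      # (1 - alpha)-weighted regularized LLE vector => columns sum to 1
      Wi <- Vi - 2 * tcrossprod(as.vector(Vi %*% h), h) +
        (1 - alpha) * matrix(w_reg[i, ], t, s)
    }
    s_all[i] <- s
    Wlist[[i]] <- Wi
    nbr <- g$indices[i, ]
    M[nbr, nbr] <- M[nbr, nbr] + tcrossprod(Wi)
    rs <- rowSums(Wi)
    M[i, nbr] <- M[i, nbr] - rs
    M[nbr, i] <- M[nbr, i] - rs
    M[i, i] <- M[i, i] + s
  }

  .embed_from_alignment(
    M, m, method = "mlle",
    params = list(t = t, m = m, tolerance = tolerance, eta = eta,
                  single_weight = single_weight),
    extra = list(s = s_all, weights = Wlist, indices = g$indices)
  )
}
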