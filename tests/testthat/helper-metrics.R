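# independent metrics used to judge embeddings and clusterings; kept free of
# the package's own fast paths

# trustworthiness: how well the embedding's k-neighborhoods are drawn from
# the original space's k-neighborhoods (1 = perfect)
trustworthiness <- function(X, Y, k) {
  n <- nrow(X)
  DX <- as.matrix(dist(X))
  DY <- as.matrix(dist(Y))
  rank_X <- t(apply(DX, 1L, function(r) rank(r, ties.method = "first")))
  acc <- 0
  for (i in seq_len(n)) {
    ordY <- order(DY[i, ], seq_len(n)); ordY <- ordY[ordY != i][seq_len(k)]
    ordX <- order(DX[i, ], seq_len(n)); ordX <- ordX[ordX != i][seq_len(k)]
    U <- setdiff(ordY, ordX)
    if (length(U)) acc <- acc + sum(rank_X[i, U] - 1L - k)
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * acc
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# relative Frobenius residual after the best orthogonal alignment of Y1 to Y2
procrustes_residual <- function(Y1, Y2) {
  s <- svd(crossprod(Y1, Y2))
  R <- s$u %*% t(s$v)
  sqrt(sum((Y1 %*% R - Y2)^2) / sum(Y2^2))
}

rel_err <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.eps)
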