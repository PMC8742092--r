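#' Exact t-nearest-neighbor graph
#'
#' Computes, for every point, its `t` nearest neighbors by Euclidean
#' distance (exact, all pairs). A point is never its own neighbor; rows are
#' sorted by ascending distance with ties broken by the smaller index, so
#' the graph is deterministic even with duplicate points.
#'
#' @param X numeric matrix, n points x d features (or an
#'   [expression_matrix()] / embedding, whose `values`/`Y` are used).
#' @param t number of neighbors, `1 <= t < n`.
#' @return A `NeighborGraph` list with `indices` (n x t integer), `distances`
#'   (n x t), and `t`.
#' @export
knn_graph <- function(X, t) {
  X <- .as_coords(X)
  n <- nrow(X)
  t <- as.integer(t)
  if (t < 1L || t >= n) {
    stop(sprintf("parameter error: need 1 <= t < n, got t=%d, n=%d", t, n))
  }
  D <- as.matrix(dist(X))
  idx <- matrix(0L, n, t)
  dst <- matrix(0, n, t)
  ord_base <- seq_len(n)
  for (i in seq_len(n)) {
    o <- order(D[i, ], ord_base)        # ascending distance, then index
    o <- o[o != i][seq_len(t)]
    idx[i, ] <- o
    dst[i, ] <- D[i, o]
  }
  structure(list(indices = idx, distances = dst, t = t, n = n),
            class = "NeighborGraph")
}

# coerce the accepted input containers to a plain coordinate matrix
.as_coords <- function(X) {
  if (inherits(X, "ExpressionMatrix")) return(X$values)
  if (inherits(X, "Embedding")) return(X$Y)
  as.matrix(X)
}
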