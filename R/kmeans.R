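#' k-means clustering with k-means++ seeding and restarts
#'
#' Lloyd's algorithm minimizing the within-cluster sum of squared distances
#' to centroids (SSE). Each of `n_init` restarts is seeded by k-means++
#' (`init = "plusplus"`) or by `k` points drawn uniformly
#' (`init = "random"`); the restart with the lowest final SSE is returned.
#' Iterations stop when the maximum centroid displacement falls below `tol`
#' or after `max_iter` iterations. An empty cluster is repaired by moving
#' the point farthest from the centroid of the largest cluster into it.
#'
#' @param X numeric matrix n x m (or an `Embedding`).
#' @param k number of clusters, `1 <= k <= n`.
#' @param n_init number of restarts (default 10).
#' @param seed integer seed; fixes the whole run.
#' @param max_iter maximum Lloyd iterations per restart (default 300).
#' @param tol centroid-displacement convergence threshold (default 1e-6).
#' @param init `"plusplus"` (default) or `"random"`.
#' @return A `ClusterAssignment` list: `labels` (1..k), `centroids` (k x m),
#'   `k`, `sse`, `sse_trace` (per-iteration SSE of the winning restart),
#'   `sse_traces` (all restarts), `n_iter`, `seed`, `n_init`.
#' @export
kmeans_cluster <- function(X, k, n_init = 10L, seed = 0L, max_iter = 300L,
                           tol = 1e-6, init = c("plusplus", "random")) {
  X <- .as_coords(X)
  init <- match.arg(init)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("parameter error: k must be >= 1")
  if (k > n) stop(sprintf("parameter error: k=%d exceeds n=%d", k, n))
  set.seed(as.integer(seed))

  best <- NULL
  traces <- vector("list", n_init)
  for (r in seq_len(n_init)) {
    run <- .lloyd_once(X, k, max_iter, tol, init)
    traces[[r]] <- run$trace
    if (is.null(best) || run$sse < best$sse) best <- run
  }
  structure(list(labels = best$labels, centroids = best$centroids, k = k,
                 sse = best$sse, sse_trace = best$trace,
                 sse_traces = traces, n_iter = best$n_iter,
                 seed = as.integer(seed), n_init = as.integer(n_init)),
            class = "ClusterAssignment")
}

.lloyd_once <- function(X, k, max_iter, tol, init) {
  n <- nrow(X)
  C <- if (init == "plusplus") .kmeanspp_init(X, k) else
    X[sample.int(n, k), , drop = FALSE]
  trace <- numeric(0)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    D2 <- .dist2_to_centroids(X, C)
    labels <- max.col(-D2, ties.method = "first")
    # repair empty clusters from the largest cluster's farthest member
    for (j in which(tabulate(labels, k) == 0L)) {
      big <- which.max(tabulate(labels, k))
      members <- which(labels == big)
      far <- members[which.max(D2[cbind(members, labels[members])])]
      labels[far] <- j
    }
    Cnew <- C
    for (j in seq_len(k)) {
      Cnew[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    }
    trace <- c(trace, .sse_of(X, labels, Cnew))
    shift <- sqrt(max(rowSums((Cnew - C)^2)))
    C <- Cnew
    if (shift < tol) break
  }
  list(labels = labels, centroids = C, sse = trace[length(trace)],
       trace = trace, n_iter = length(trace))
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    D2 <- .dist2_to_centroids(X, X[idx, , drop = FALSE])
    d2min <- apply(D2, 1L, min)
    d2min[idx] <- 0
    if (sum(d2min) <= 0) {
      cand <- setdiff(seq_len(n), idx)
      idx <- c(idx, cand[sample.int(length(cand), 1L)])
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2min / sum(d2min)))
    }
  }
  X[idx, , drop = FALSE]
}

# n x k matrix of squared Euclidean distances to each centroid
.dist2_to_centroids <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

.sse_of <- function(X, labels, C) {
  sum((X - C[labels, , drop = FALSE])^2)
}

#' Within-cluster sum of squared errors
#'
#' Recomputes the k-means objective: the sum over points of the squared
#' Euclidean distance to the centroid of their assigned cluster.
#'
#' @param X numeric matrix n x m (or an `Embedding`).
#' @param assignment a `ClusterAssignment` (its `labels` and `centroids` are
#'   used), or an integer label vector, in which case centroids are the
#'   label-wise means.
#' @return The scalar SSE.
#' @export
sse <- function(X, assignment) {
  X <- .as_coords(X)
  if (inherits(assignment, "ClusterAssignment")) {
    labels <- assignment$labels
    C <- assignment$centroids
  } else {
    labels <- as.integer(assignment)
    k <- max(labels)
    C <- matrix(0, k, ncol(X))
    for (j in seq_len(k)) C[j, ] <- colMeans(X[labels == j, , drop = FALSE])
  }
  if (any(labels < 1L) || any(labels > nrow(C))) {
    stop("validation error: cluster label out of range")
  }
  .sse_of(X, labels, C)
}
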