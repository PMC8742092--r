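#' Mean Silhouette coefficient
#'
#' For each point, `SH = (b - w) / max(w, b)` where `w` is the mean
#' Euclidean distance to the other members of its own cluster and `b` is the
#' minimum over other clusters of the mean distance to that cluster's
#' members. A point in a singleton cluster contributes 0 (standard
#' convention). The returned score is the mean over all points and lies in
#' `[-1, 1]`; higher is better.
#'
#' @param X numeric matrix n x m (or an `Embedding`).
#' @param labels cluster labels (any atomic type); at least 2 clusters.
#' @return Mean Silhouette coefficient.
#' @export
silhouette_score <- function(X, labels) {
  X <- .as_coords(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("parameter error: silhouette requires k >= 2")
  n <- nrow(X)
  D <- as.matrix(dist(X))
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster (including own, self term 0)
  sums <- matrix(0, n, k)
  for (j in seq_len(k)) {
    sums[, j] <- rowSums(D[, labels == j, drop = FALSE])
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    w <- sums[i, ci] / (sizes[ci] - 1L)
    b <- min((sums[i, -ci] / sizes[-ci]))
    s[i] <- if (max(w, b) > 0) (b - w) / max(w, b) else 0
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `CH = tr(S_B) / tr(S_W) * (n - k) / (k - 1)` with
#' `tr(S_B) = sum_j n_j ||mu_j - mu||^2` and
#' `tr(S_W) = sum_j sum_{i in C_j} ||x_i - mu_j||^2`. Higher is better.
#' A perfect within-cluster fit (`tr(S_W) = 0`) returns `Inf` with a
#' warning.
#'
#' @inheritParams silhouette_score
#' @return The CH score (>= 0).
#' @export
calinski_harabasz <- function(X, labels) {
  X <- .as_coords(X)
  labels <- as.integer(factor(labels))
  k <- max(labels); n <- nrow(X)
  if (k < 2L || k >= n) {
    stop("parameter error: Calinski-Harabasz requires 2 <= k < n")
  }
  mu <- colMeans(X)
  tr_b <- 0; tr_w <- 0
  for (j in seq_len(k)) {
    Xi <- X[labels == j, , drop = FALSE]
    mj <- colMeans(Xi)
    tr_b <- tr_b + nrow(Xi) * sum((mj - mu)^2)
    tr_w <- tr_w + sum(sweep(Xi, 2L, mj)^2)
  }
  if (tr_w == 0) {
    warning("within-cluster dispersion is zero; CH is infinite")
    return(Inf)
  }
  (tr_b / tr_w) * (n - k) / (k - 1)
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) sum_i max_{j != i} (w_i + w_j) / d_ij` where `w_i` is the
#' mean Euclidean distance of the members of cluster i to its centroid and
#' `d_ij` the distance between centroids. Lower is better.
#'
#' @inheritParams silhouette_score
#' @return The DB score (>= 0).
#' @export
davies_bouldin <- function(X, labels) {
  X <- .as_coords(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("parameter error: Davies-Bouldin requires k >= 2")
  C <- matrix(0, k, ncol(X))
  w <- numeric(k)
  for (j in seq_len(k)) {
    Xi <- X[labels == j, , drop = FALSE]
    C[j, ] <- colMeans(Xi)
    w[j] <- mean(sqrt(rowSums(sweep(Xi, 2L, C[j, ])^2)))
  }
  dcent <- as.matrix(dist(C))
  if (any(dcent[upper.tri(dcent)] == 0)) {
    pr <- which(dcent == 0 & upper.tri(dcent), arr.ind = TRUE)[1L, ]
    stop(sprintf("coincident centroids for clusters %d and %d", pr[1], pr[2]))
  }
  db <- 0
  for (i in seq_len(k)) {
    sij <- (w[i] + w[-i]) / dcent[i, -i]
    db <- db + max(sij)
  }
  db / k
}

#' Brute-force validity oracle
#'
#' Computes all three validity indices by direct double loops over points,
#' with no vectorized shortcuts, sharing the singleton-silhouette = 0
#' convention with the fast implementations. Intended as an independent
#' reference in tests; restricted to `n <= 500`.
#'
#' @inheritParams silhouette_score
#' @return A `ValidityScores` list: `silhouette`, `calinski_harabasz`,
#'   `davies_bouldin`.
#' @export
validity_oracle <- function(X, labels) {
  X <- .as_coords(X)
  labels <- as.integer(factor(labels))
  n <- nrow(X)
  if (n > 500L) stop("validity_oracle is O(n^2); use n <= 500")
  k <- max(labels)
  if (k < 2L) stop("parameter error: need k >= 2")
  d <- function(a, b) sqrt(sum((X[a, ] - X[b, ])^2))

  # silhouette
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- 0; n_own <- 0L
    others <- rep(0, k); n_oth <- integer(k)
    for (j in seq_len(n)) {
      if (j == i) next
      if (labels[j] == labels[i]) {
        own <- own + d(i, j); n_own <- n_own + 1L
      }
    }
    for (cl in seq_len(k)) {
      if (cl == labels[i]) next
      for (j in seq_len(n)) {
        if (labels[j] == cl) {
          others[cl] <- others[cl] + d(i, j)
          n_oth[cl] <- n_oth[cl] + 1L
        }
      }
    }
    if (n_own == 0L) { sil[i] <- 0; next }
    w <- own / n_own
    b <- Inf
    for (cl in seq_len(k)) {
      if (cl != labels[i] && n_oth[cl] > 0L) {
        b <- min(b, others[cl] / n_oth[cl])
      }
    }
    sil[i] <- if (max(w, b) > 0) (b - w) / max(w, b) else 0
  }

  # centroids and global mean, by loops
  p <- ncol(X)
  cent <- matrix(0, k, p)
  sizes <- integer(k)
  for (i in seq_len(n)) {
    cent[labels[i], ] <- cent[labels[i], ] + X[i, ]
    sizes[labels[i]] <- sizes[labels[i]] + 1L
  }
  for (cl in seq_len(k)) cent[cl, ] <- cent[cl, ] / sizes[cl]
  gmu <- colSums(X) / n

  tr_b <- 0; tr_w <- 0
  for (cl in seq_len(k)) tr_b <- tr_b + sizes[cl] * sum((cent[cl, ] - gmu)^2)
  for (i in seq_len(n)) tr_w <- tr_w + sum((X[i, ] - cent[labels[i], ])^2)
  ch <- if (tr_w == 0) Inf else (tr_b / tr_w) * (n - k) / (k - 1)

  wscat <- numeric(k)
  for (cl in seq_len(k)) {
    acc <- 0
    for (i in seq_len(n)) {
      if (labels[i] == cl) acc <- acc + sqrt(sum((X[i, ] - cent[cl, ])^2))
    }
    wscat[cl] <- acc / sizes[cl]
  }
  db <- 0
  for (i in seq_len(k)) {
    worst <- 0
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      worst <- max(worst, (wscat[i] + wscat[j]) / dij)
    }
    db <- db + worst
  }
  db <- db / k

  structure(list(silhouette = mean(sil), calinski_harabasz = ch,
                 davies_bouldin = db),
            class = "ValidityScores")
}

#' All three validity indices at once
#'
#' @inheritParams silhouette_score
#' @return A `ValidityScores` list: `silhouette`, `calinski_harabasz`,
#'   `davies_bouldin`.
#' @export
validity_scores <- function(X, labels) {
  structure(list(silhouette = silhouette_score(X, labels),
                 calinski_harabasz = calinski_harabasz(X, labels),
                 davies_bouldin = davies_bouldin(X, labels)),
            class = "ValidityScores")
}
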