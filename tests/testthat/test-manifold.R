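test_that("exact kNN matches brute force with the deterministic tie rule", {
  X <- matrix(c(0, 1, 3, 7), 4, 1)
  g <- knn_graph(X, 2)
  expect_equal(g$indices[3, ], c(2L, 1L))     # neighbors of 3 are {1, 0}
  expect_equal(g$distances[3, ], c(2, 3))

  two <- knn_graph(matrix(c(0, 5), 2, 1), 1)
  expect_equal(two$indices[, 1], c(2L, 1L))

  expect_error(knn_graph(X, 4), "t < n")

  # duplicates: smaller index wins, repeat runs identical
  Xd <- matrix(c(0, 0, 0, 2), 4, 1)
  g1 <- knn_graph(Xd, 2)
  g2 <- knn_graph(Xd, 2)
  expect_identical(g1$indices, g2$indices)
  expect_equal(g1$indices[1, ], c(2L, 3L))
})

test_that("the kNN graph is invariant under rigid rotation", {
  set.seed(9)
  X <- matrix(rnorm(40 * 3), 40, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  g1 <- knn_graph(X, 5)
  g2 <- knn_graph(X %*% R, 5)
  expect_equal(g1$indices, g2$indices)
})

test_that("reconstruction weights sum to one and solve the midpoint exactly", {
  X <- rbind(c(0, 0), c(-1, 0), c(1, 0))
  w <- lle_weights(X, knn_graph(X, 2), tolerance = 1e-3)
  expect_equal(as.numeric(w$W[1, 2:3]), c(0.5, 0.5), tolerance = 1e-12)
  expect_true(all(abs(Matrix::rowSums(w$W) - 1) <= 1e-10))
})

test_that("weights reconstruct points inside the affine hull of neighbors", {
  set.seed(12)
  nbrs <- matrix(rnorm(12), 4, 3)
  coef <- runif(4); coef <- coef / sum(coef)
  x <- colSums(coef * nbrs)
  X <- rbind(x, nbrs)
  w <- lle_weights(X, knn_graph(X, 4), tolerance = 1e-12)
  recon <- as.numeric(w$W[1, 2:5] %*% nbrs)
  expect_lte(sqrt(sum((x - recon)^2)), 1e-8)
})

test_that("solved weights beat random feasible weight vectors", {
  set.seed(13)
  X <- matrix(rnorm(6 * 3), 6, 3)
  g <- knn_graph(X, 5)
  w <- lle_weights(X, g, tolerance = 1e-10)
  i <- 1L
  nbrs <- X[g$indices[i, ], ]
  resid <- sqrt(sum((X[i, ] - as.numeric(w$W[i, g$indices[i, ]] %*% nbrs))^2))
  rand <- matrix(rnorm(10000 * 5), 10000, 5)
  rand <- rand / rowSums(rand)
  keep <- is.finite(rowSums(rand)) & abs(rowSums(rand) - 1) < 1e-9
  rec <- rand[keep, , drop = FALSE] %*% nbrs
  rand_resid <- sqrt(rowSums(sweep(rec, 2, X[i, ])^2))
  expect_lte(resid, min(rand_resid) + 1e-12)
})

test_that("LLE cost equals the retained eigenvalues and beats random frames", {
  set.seed(14)
  X <- matrix(rnorm(50 * 4), 50, 4)
  w <- lle_weights(X, knn_graph(X, 6))
  emb <- lle_embed(w, 2)
  cost <- embedding_cost(emb, emb$Y)
  expect_equal(cost, sum(emb$details$eigenvalues), tolerance = 1e-8)
  for (r in 1:100) {
    Yr <- qr.Q(qr(matrix(rnorm(50 * 2), 50, 2)))
    expect_lte(cost, embedding_cost(emb, Yr) + 1e-10)
  }
  # orthonormal coordinates with near-zero means
  expect_equal(crossprod(emb$Y), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(emb$Y)) <= 1e-6))
})

test_that("LLE unrolls a noiseless one-dimensional curve", {
  u <- seq(0, 2, length.out = 40)
  X <- cbind(cos(u), sin(u), 0.5 * u)
  w <- lle_weights(X, knn_graph(X, 4))
  emb <- lle_embed(w, 1)
  expect_gte(abs(cor(emb$Y[, 1], u, method = "spearman")), 0.99)
})

test_that("MLLE orders an irregularly sampled curve where LLE wobbles", {
  # irregular spacing makes single-weight LLE sensitive to the
  # regularization scale; the multi-weight construction is not
  set.seed(15)
  u <- sort(runif(40, 0, 2))
  X <- cbind(cos(u), sin(u), 0.5 * u)
  emb <- mlle_embed(X, t = 4, m = 1)
  expect_gte(abs(cor(emb$Y[, 1], u, method = "spearman")), 0.99)
})

test_that("embeddings are invariant to translating the input", {
  set.seed(16)
  X <- matrix(rnorm(30 * 3), 30, 3)
  sh <- matrix(5, 30, 3)
  e1 <- mlle_embed(X, t = 6, m = 2)
  e2 <- mlle_embed(X + sh, t = 6, m = 2)
  expect_equal(e1$Y, e2$Y, tolerance = 1e-6)
})

test_that("MLLE embeds an affine low-rank dataset with vanishing cost", {
  set.seed(17)
  Z <- matrix(rnorm(60 * 2), 60, 2)
  lift <- matrix(rnorm(2 * 5), 2, 5)
  X <- Z %*% lift + matrix(1, 60, 1) %*% rnorm(5)
  emb <- mlle_embed(X, t = 8, m = 2, tolerance = 1e-12)
  expect_lte(embedding_cost(emb, emb$Y), 1e-6)
})

test_that("every MLLE weight vector sums to one", {
  set.seed(18)
  X <- matrix(rnorm(40 * 5), 40, 5)
  emb <- mlle_embed(X, t = 7, m = 3)
  for (Wi in emb$details$weights) {
    expect_true(all(abs(colSums(Wi) - 1) <= 1e-10))
  }
  expect_true(all(emb$details$s >= 1))
  expect_true(all(emb$details$s <= 7 - 3))
})

test_that("MLLE rejects t <= m", {
  X <- matrix(rnorm(20 * 4), 20, 4)
  expect_error(mlle_embed(X, t = 3, m = 3), "t > m")
})

test_that("single-weight MLLE reproduces standard LLE up to orthogonality", {
  set.seed(19)
  X <- matrix(rnorm(35 * 4), 35, 4)
  e_m <- mlle_embed(X, t = 6, m = 2, tolerance = 1e-3, single_weight = TRUE)
  e_l <- lle_embed(lle_weights(X, knn_graph(X, 6), tolerance = 1e-3), 2)
  expect_lte(procrustes_residual(e_m$Y, e_l$Y), 1e-6)
})

test_that("PCA satisfies its spectral identities", {
  set.seed(20)
  # collinear points: one component carries all variance
  line <- outer(rnorm(30), c(1, -2, 0.5, 3, 2))
  p1 <- pca_embed(line, 2)
  ev <- p1$details$eigenvalues
  expect_equal(ev[1] / sum(ev), 1, tolerance = 1e-12)

  X <- matrix(rnorm(25 * 4), 25, 4)
  p <- pca_embed(X, 4)
  total_var <- sum(apply(X, 2, function(x) mean(x^2) - mean(x)^2))
  expect_equal(sum(p$details$eigenvalues), total_var, tolerance = 1e-10)
  # full-rank reconstruction
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(p$Y %*% t(p$details$components), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign: largest loading of each component is positive
  for (j in 1:4) {
    expect_gt(p$details$components[which.max(abs(p$details$components[, j])), j], 0)
  }
})
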