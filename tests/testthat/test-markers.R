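test_that("the rank-sum statistic matches exhaustive enumeration", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  lab <- c(1, 1, 1, 2, 2, 2, 2)
  tbl <- rank_markers(matrix(x, 7, 1, dimnames = list(NULL, "g")), lab,
                      n_top = 1)
  W_in <- tbl$rank_sum[tbl$cluster == "1"]
  expect_equal(W_in, sum(rank(x)[1:3]))    # = 6, the minimum possible
  # enumeration over all 35 assignments of 3 of 7 ranks to the in-group
  combos <- combn(7, 3)
  all_W <- colSums(matrix(rank(x)[combos], 3))
  expect_equal(W_in, min(all_W))
  expect_equal(mean(all_W <= W_in), 1 / 35)   # exact one-sided tail
  expect_lt(tbl$z_statistic[tbl$cluster == "1"], 0)
})

test_that("normal-approximation p-values agree with stats::wilcox.test", {
  set.seed(41)
  for (r in 1:20) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    x <- c(sample.int(8, n1, TRUE), sample.int(8, n2, TRUE) + r %% 3)
    lab <- rep(1:2, c(n1, n2))
    tbl <- rank_markers(matrix(as.numeric(x), ncol = 1,
                               dimnames = list(NULL, "g")), lab,
                        n_top = 1)
    ref <- stats::wilcox.test(x[lab == 1], x[lab == 2], exact = FALSE,
                              correct = FALSE)
    expect_equal(tbl$p_value[tbl$cluster == "1"], ref$p.value,
                 tolerance = 1e-10)
  }
})

test_that("planted up-regulated genes surface in the cluster's top markers", {
  # 50 genes shifted up by 2 log-units in cluster 1 only
  sim <- make_nb_counts(K = 2, n_cells = 200, n_genes = 500, de_frac = 0.1,
                        lfc = 2, seed = 42, de_sign = "up",
                        de_clusters = 1)
  norm <- cpm_lognormalize(sim$counts)
  tbl <- rank_markers(norm$values, sim$truth$labels, n_top = 50)
  planted <- sim$counts$gene_names[sim$truth$de_mask[1, ]]
  expect_length(planted, 50)
  hits <- sum(planted %in% tbl$gene_name[tbl$cluster == "1"])
  expect_gte(hits, 0.9 * length(planted))
})

test_that("flat genes score zero and never outrank real markers", {
  set.seed(43)
  X <- cbind(flat = rep(3, 40), up = c(rnorm(20, 5), rnorm(20, 0)))
  lab <- rep(1:2, each = 20)
  tbl <- rank_markers(X, lab, n_top = 1)
  expect_equal(tbl$gene_name, c("up", "up"))
  full <- rank_markers(X, lab, n_top = 2)
  flat_rows <- full[full$gene_name == "flat", ]
  expect_equal(flat_rows$z_statistic, c(0, 0))
  expect_equal(flat_rows$p_value, c(1, 1))
})

test_that("the z statistic is invariant under monotone transforms, the fold change is not", {
  set.seed(44)
  X <- matrix(rlnorm(60 * 5), 60, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  lab <- rep(1:2, each = 30)
  t1 <- rank_markers(X, lab, n_top = 5)
  t2 <- rank_markers(exp(X), lab, n_top = 5)
  o1 <- order(t1$cluster, t1$gene_name)
  o2 <- order(t2$cluster, t2$gene_name)
  expect_equal(t1$z_statistic[o1], t2$z_statistic[o2], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(t1$log_fold_change[o1],
                                t2$log_fold_change[o2])))
})

test_that("adjusted p-values dominate raw ones and stay in [0, 1]", {
  set.seed(45)
  X <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(NULL, paste0("g", 1:30)))
  lab <- rep(1:2, each = 25)
  tbl <- rank_markers(X, lab, n_top = 30)
  expect_true(all(tbl$adjusted_p >= tbl$p_value - 1e-15))
  expect_true(all(tbl$adjusted_p >= 0 & tbl$adjusted_p <= 1))
  expect_true(all(tbl$p_value >= 0 & tbl$p_value <= 1))
})

test_that("tiny clusters are skipped with a warning", {
  set.seed(46)
  X <- matrix(rnorm(21 * 3), 21, 3, dimnames = list(NULL, paste0("g", 1:3)))
  lab <- c(rep(1, 10), rep(2, 10), 3)
  expect_warning(tbl <- rank_markers(X, lab, n_top = 3), "fewer than 2")
  expect_false("3" %in% tbl$cluster)
})

test_that("exported gene lists are verbatim and ordered", {
  set.seed(47)
  X <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(NULL, paste0("GeNe", 1:25)))
  lab <- rep(1:2, each = 20)
  tbl <- rank_markers(X, lab, n_top = 20)
  d <- withr::local_tempdir()
  files <- export_gene_lists(tbl, d, format = "rnk")
  expect_length(files, 2)
  for (f in files) {
    rnk <- read.delim(f, header = FALSE)
    expect_equal(nrow(rnk), 20)
    expect_true(all(rnk$V1 %in% colnames(X)))      # case preserved
    expect_true(all(diff(rnk$V2) <= 0))            # descending z
  }
  grp <- export_gene_lists(tbl, d, format = "grp")
  expect_equal(length(readLines(grp[1])), 20)
})
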