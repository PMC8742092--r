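#' Grid sweep over embedding and clustering parameters
#'
#' For every combination of neighborhood size `t`, embedding dimension `m`
#' and regularization tolerance, the cells are embedded once with MLLE
#' (optionally followed by FastICA); for every cluster number `k` the
#' embedding is then clustered by k-means and scored with the Silhouette,
#' Calinski-Harabasz and Davies-Bouldin indices, so all `k` records of a
#' configuration share the identical embedding. Scores are computed in the
#' space used for clustering (`cluster_space`). Infeasible cells (`t <= m`)
#' are skipped with a logged reason. The shipped default grids are
#' `t = 8..24` and `k = 4..14`.
#'
#' @param X numeric matrix of cell coordinates (typically the scaled
#'   HVG expression matrix), or an [expression_matrix()].
#' @param t_grid neighborhood sizes (default `8:24`).
#' @param k_grid cluster numbers (default `4:14`).
#' @param m_grid embedding dimensions (default 3).
#' @param tol_grid regularization tolerances (default decades
#'   `1e-12 .. 1e-3`).
#' @param seed base seed; per-configuration seeds are derived from it.
#' @param use_ica apply FastICA to the MLLE embedding (default TRUE).
#' @param ica_dims ICA components when `use_ica` (default 2).
#' @param cluster_space `"ica"` (default; falls back to `"mlle"` when
#'   `use_ica = FALSE`) or `"mlle"`: the space in which k-means runs and the
#'   indices are scored.
#' @param n_init k-means restarts per record (default 10).
#' @param rule selection rule passed to [select_best()].
#' @return A `SweepResult`: `records` (data.frame with columns t, m,
#'   tolerance, k, sh, ch, db, sse, seed), `chosen` (the selected record),
#'   `labels` (cluster labels of the chosen record), `selection_rule`, and
#'   `skipped` (data.frame of infeasible cells and reasons).
#' @export
sweep_grid <- function(X, t_grid = 8:24, k_grid = 4:14, m_grid = 3L,
                       tol_grid = 10^seq(-12, -3), seed = 0L,
                       use_ica = TRUE, ica_dims = 2L,
                       cluster_space = c("ica", "mlle"), n_init = 10L,
                       rule = c("sh_primary", "rank_sum")) {
  X <- .as_coords(X)
  cluster_space <- match.arg(cluster_space)
  rule <- match.arg(rule)
  stopifnot(length(t_grid) > 0, length(k_grid) > 0, length(m_grid) > 0,
            length(tol_grid) > 0)
  if (!use_ica) cluster_space <- "mlle"

  records <- list()
  labels_store <- list()
  skipped <- list()
  cfg_id <- 0L
  for (m in m_grid) for (tol in tol_grid) for (tt in t_grid) {
    cfg_id <- cfg_id + 1L
    if (tt <= m) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        t = tt, m = m, tolerance = tol,
        reason = "infeasible: t <= m", stringsAsFactors = FALSE)
      next
    }
    emb <- mlle_embed(X, t = tt, m = m, tolerance = tol)
    space <- emb$Y
    if (use_ica) {
      ic <- fastica(emb, n_components = min(ica_dims, m),
                    seed = .derive_seed(seed, cfg_id))
      if (cluster_space == "ica") space <- ic$embedding$Y
    }
    for (k in k_grid) {
      res <- tryCatch({
        cl <- kmeans_cluster(space, k = k, n_init = n_init,
                             seed = .derive_seed(seed, cfg_id, k))
        list(rec = data.frame(
          t = tt, m = m, tolerance = tol, k = k,
          sh = silhouette_score(space, cl$labels),
          ch = suppressWarnings(calinski_harabasz(space, cl$labels)),
          db = davies_bouldin(space, cl$labels),
          sse = cl$sse, seed = cl$seed), labels = cl$labels)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        # degenerate cells (e.g. coincident centroids at large k on
        # collapsed embeddings) are logged, not fatal
        skipped[[length(skipped) + 1L]] <- data.frame(
          t = tt, m = m, tolerance = tol,
          reason = sprintf("k=%d failed: %s", k, res),
          stringsAsFactors = FALSE)
        next
      }
      records[[length(records) + 1L]] <- res$rec
      labels_store[[length(labels_store) + 1L]] <- res$labels
    }
  }
  if (length(records) == 0L) stop("all sweep cells were infeasible")
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  best <- select_best(records, rule = rule)
  structure(list(
    records = records,
    chosen = records[best, , drop = FALSE],
    labels = labels_store[[best]],
    selection_rule = rule,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    seed = as.integer(seed)
  ), class = "SweepResult")
}

# deterministic per-configuration seed below 2^31
.derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(c(...)))
  acc <- 0
  for (p in parts) acc <- (acc * 7919 + p + 1) %% 2147483647
  as.integer(acc)
}

#' Select the best sweep record
#'
#' `sh_primary` (default): maximize the Silhouette score, breaking ties by
#' higher CH, then lower DB, then smaller k, then smaller t. `rank_sum`:
#' minimize the summed ranks of (-SH, -CH, DB) with the same tie cascade.
#'
#' @param records a `SweepResult` or its `records` data.frame.
#' @param rule `"sh_primary"` or `"rank_sum"`.
#' @return The integer row index of the selected record.
#' @export
select_best <- function(records, rule = c("sh_primary", "rank_sum")) {
  rule <- match.arg(rule)
  if (inherits(records, "SweepResult")) records <- records$records
  if (nrow(records) == 0L) stop("no records to select from")
  if (rule == "sh_primary") {
    o <- order(-records$sh, -records$ch, records$db, records$k, records$t)
  } else {
    score <- rank(-records$sh) + rank(-records$ch) + rank(records$db)
    o <- order(score, -records$sh, -records$ch, records$db, records$k,
               records$t)
  }
  o[1L]
}

#' Elbow (knee) selection on a score-vs-k curve
#'
#' Scores typically decrease as k grows; the elbow is the point of maximum
#' curvature, automated here as the k whose point has maximal perpendicular
#' distance from the chord joining the first and last (k, score) points.
#' Exactly collinear profiles carry no elbow: the first k is returned with
#' `no_elbow = TRUE` and a warning.
#'
#' @param k ordered vector of at least 3 distinct cluster numbers.
#' @param score finite scores, same length as `k`.
#' @return A list with `k_star`, `distances` (the chord-distance profile)
#'   and `no_elbow`.
#' @export
elbow_select <- function(k, score) {
  stopifnot(length(k) == length(score))
  if (length(unique(k)) < 3L) {
    stop("parameter error: elbow selection needs >= 3 distinct k values")
  }
  if (any(!is.finite(score))) stop("parameter error: scores must be finite")
  o <- order(k)
  k <- as.numeric(k[o]); score <- as.numeric(score[o])
  p1 <- c(k[1L], score[1L])
  p2 <- c(k[length(k)], score[length(k)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  dx <- k - p1[1L]; dy <- score - p1[2L]
  dist <- abs(v[1L] * dy - v[2L] * dx) / nv
  no_elbow <- max(dist) < 1e-9
  if (no_elbow) {
    warning("score profile is collinear; no elbow found")
    k_star <- k[1L]
  } else {
    k_star <- k[which.max(dist)]
  }
  list(k_star = k_star, distances = dist, no_elbow = no_elbow)
}
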