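#' Run the full cell-type discovery pipeline
#'
#' Executes QC -> CPM/log normalization -> HVG selection -> covariate
#' regression -> unit-variance scaling -> MLLE -> (optional) FastICA ->
#' k-means (at a fixed `k`, or a parameter sweep when `cfg$k` is `NA`) ->
#' validity scoring -> marker ranking. When `out` is given, each stage
#' writes its artifact there (filtered counts, HVG mask, embedding and
#' labels CSVs, marker table, summary and provenance JSON). Covariates for
#' the regression stage are the per-cell total counts and mitochondrial
#' percentage of the QC-filtered matrix. Clustering (and index scoring)
#' happens in the ICA space when ICA is enabled and
#' `cfg$cluster_space == "ica"`, otherwise in the MLLE space; the space used
#' is recorded in the summary.
#'
#' @param input a [count_matrix()], or a path readable by [read_counts()].
#' @param cfg a `RunConfig` from [default_config()] / [load_config()].
#' @param out optional output directory for stage artifacts.
#' @return A `PipelineRun` list: `config`, `qc_report`, `hvg_mask`,
#'   `embedding`, `ica` (or NULL), `clustering`, `scores`, `markers`,
#'   `sweep` (or NULL), `cluster_space`, `summary`.
#' @export
run_pipeline <- function(input, cfg = default_config(), out = NULL) {
  counts <- if (inherits(input, "CountMatrix")) input else read_counts(input)

  qc <- qc_filter(counts,
                  min_cells_per_gene = cfg$min_cells_per_gene,
                  min_genes_per_cell = cfg$min_genes_per_cell,
                  max_mito_pct = cfg$max_mito_pct,
                  mito_prefix = cfg$mito_prefix)
  norm <- cpm_lognormalize(qc$counts)
  hv <- select_hvgs(norm, n_bins = cfg$n_bins, min_disp = cfg$min_disp,
                    min_mean = cfg$min_mean, max_mean = cfg$max_mean)
  expr <- hv$expr
  if (isTRUE(cfg$regress)) {
    totals <- Matrix::rowSums(qc$counts$values)
    is_mito <- startsWith(toupper(qc$counts$gene_names),
                          toupper(cfg$mito_prefix))
    mito_pct <- if (any(is_mito)) {
      100 * Matrix::rowSums(qc$counts$values[, is_mito, drop = FALSE]) /
        totals
    } else rep(0, length(totals))
    expr <- suppressWarnings(
      regress_out(expr, cbind(total_counts = totals, mito_pct = mito_pct)))
  }
  scaled <- scale_unit_variance(expr, clip_max = cfg$clip_max)

  sweep_res <- NULL
  if (is.na(cfg$k)) {
    sweep_res <- sweep_grid(scaled$values, t_grid = cfg$t_grid,
                            k_grid = cfg$k_grid, m_grid = cfg$m_grid,
                            tol_grid = cfg$tol_grid, seed = cfg$seed,
                            use_ica = cfg$use_ica, ica_dims = cfg$ica_dims,
                            cluster_space = cfg$cluster_space,
                            n_init = cfg$n_init,
                            rule = cfg$selection_rule)
    chosen <- sweep_res$chosen
    t_use <- chosen$t; m_use <- chosen$m
    tol_use <- chosen$tolerance; k_use <- chosen$k
  } else {
    t_use <- cfg$neighbors; m_use <- cfg$dims
    tol_use <- cfg$tolerance; k_use <- cfg$k
  }

  X_embed <- scaled$values
  if (!is.null(cfg$dims_stage1) && !is.na(cfg$dims_stage1)) {
    # two-pass reduction: first to an intermediate dimension, then down
    # to the final one
    stage1 <- mlle_embed(X_embed, t = t_use, m = cfg$dims_stage1,
                         tolerance = tol_use)
    X_embed <- stage1$Y
  }
  emb <- mlle_embed(X_embed, t = t_use, m = m_use,
                    tolerance = tol_use)
  ica <- NULL
  space <- emb$Y
  cluster_space <- "mlle"
  if (isTRUE(cfg$use_ica)) {
    ica <- fastica(emb, n_components = min(cfg$ica_dims, m_use),
                   seed = cfg$seed)
    if (identical(cfg$cluster_space, "ica")) {
      space <- ica$embedding$Y
      cluster_space <- "ica"
    }
  }
  cl <- kmeans_cluster(space, k = k_use, n_init = cfg$n_init,
                       seed = cfg$seed, max_iter = cfg$max_iter)
  scores <- validity_scores(space, cl$labels)
  markers <- rank_markers(norm$values[, hv$hvg_mask, drop = FALSE],
                          cl$labels, n_top = cfg$n_top_markers)

  summary <- list(
    n_cells = length(cl$labels),
    n_genes_hvg = sum(hv$hvg_mask),
    parameters = list(t = t_use, m = m_use, tolerance = tol_use, k = k_use,
                      cluster_space = cluster_space, seed = cfg$seed),
    scores = list(silhouette = scores$silhouette,
                  calinski_harabasz = scores$calinski_harabasz,
                  davies_bouldin = scores$davies_bouldin),
    labels = stats::setNames(as.integer(cl$labels), qc$counts$cell_ids)
  )

  run <- structure(list(
    config = cfg, qc_report = qc$report, hvg_mask = hv$hvg_mask,
    embedding = emb, ica = ica, clustering = cl, scores = scores,
    markers = markers, sweep = sweep_res, cluster_space = cluster_space,
    summary = summary
  ), class = "PipelineRun")

  if (!is.null(out)) .write_pipeline_artifacts(run, qc, out)
  run
}

.write_pipeline_artifacts <- function(run, qc, out) {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_counts(qc$counts, file.path(out, "filtered_counts"), format = "mtx")
  write.table(
    data.frame(gene = names(run$hvg_mask), hvg = run$hvg_mask),
    file.path(out, "hvg_mask.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  emb_df <- data.frame(cell_id = qc$counts$cell_ids, run$embedding$Y)
  colnames(emb_df) <- c("cell_id",
                        paste0("y", seq_len(ncol(run$embedding$Y))))
  write.table(emb_df, file.path(out, "embedding.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(cell_id = qc$counts$cell_ids,
               cluster = run$clustering$labels),
    file.path(out, "labels.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)
  write.table(run$markers, file.path(out, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- list(package = "scmanifold",
               version = as.character(packageVersion("scmanifold")),
               r_version = paste(R.version$major, R.version$minor,
                                 sep = "."),
               seed = run$config$seed,
               config = unclass(run$config))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
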