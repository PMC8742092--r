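#' @title Expression matrix container
#' @description Dense real-valued cells x genes matrix produced by the
#'   normalization stages. `stage` records the pipeline position and must
#'   advance in the order `normalized -> hvg -> regressed -> scaled`.
#' @param values dense numeric matrix, cells x genes, finite entries.
#' @param cell_ids,gene_names axis labels.
#' @param stage one of `"normalized"`, `"hvg"`, `"regressed"`, `"scaled"`.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_names = colnames(values),
                              stage = "normalized") {
  stage <- match.arg(stage, c("normalized", "hvg", "regressed", "scaled"))
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    stop("validation error: non-finite entries in expression matrix")
  }
  stopifnot(length(cell_ids) == nrow(values),
            length(gene_names) == ncol(values))
  dimnames(values) <- list(cell_ids, gene_names)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 gene_names = as.character(gene_names), stage = stage),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d cells x %d genes\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

.stage_index <- function(stage) {
  match(stage, c("normalized", "hvg", "regressed", "scaled"))
}

.check_stage <- function(e, allowed) {
  if (!e$stage %in% allowed) {
    stop(sprintf("stage error: expected stage %s, got '%s'",
                 paste(sprintf("'%s'", allowed), collapse = " or "), e$stage))
  }
}

#' Quality-control filtering of a count matrix
#'
#' Applies, in this fixed order: (1) removal of genes expressed in fewer than
#' `min_cells_per_gene` cells (support counted over all input cells); (2)
#' removal of cells expressing fewer than `min_genes_per_cell` of the
#' surviving genes; (3) removal of cells whose mitochondrial count fraction
#' (over surviving genes, genes matched case-insensitively by
#' `mito_prefix`) exceeds `max_mito_pct` percent. Low gene support flags
#' noise genes; a low expressed-gene count or a high mitochondrial fraction
#' flags dead or damaged cells.
#'
#' @param m a [count_matrix()] object.
#' @param min_cells_per_gene minimum number of cells a gene must be expressed
#'   in (default 3).
#' @param min_genes_per_cell minimum number of expressed genes per cell
#'   (default 200).
#' @param max_mito_pct maximum mitochondrial percentage per cell (default 5);
#'   `Inf` disables the mitochondrial filter.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (case-insensitive, default `"MT-"`).
#' @return A list with `counts` (filtered [count_matrix()]) and `report`, a
#'   `QCReport` list with per-stage dimensions and the per-cell QC metrics
#'   (expressed-gene counts, total counts, mitochondrial percentage) of the
#'   input cells.
#' @export
qc_filter <- function(m, min_cells_per_gene = 3L, min_genes_per_cell = 200L,
                      max_mito_pct = 5.0, mito_prefix = "MT-") {
  stopifnot(inherits(m, "CountMatrix"),
            min_cells_per_gene >= 0, min_genes_per_cell >= 0,
            max_mito_pct >= 0)
  v <- m$values
  n_cells_in <- nrow(v); n_genes_in <- ncol(v)

  # stage 1: gene support over all input cells
  support <- Matrix::colSums(v > 0)
  keep_gene <- support >= min_cells_per_gene
  if (!any(keep_gene)) stop("empty after QC: no gene passed the support filter")
  v1 <- v[, keep_gene, drop = FALSE]

  # stage 2: expressed genes per cell, over surviving genes
  genes_per_cell <- Matrix::rowSums(v1 > 0)
  keep_cell <- genes_per_cell >= min_genes_per_cell
  if (!any(keep_cell)) {
    stop("empty after QC: no cell passed the expressed-gene filter")
  }
  v2 <- v1[keep_cell, , drop = FALSE]

  # stage 3: mitochondrial fraction on surviving genes
  gene_names2 <- m$gene_names[keep_gene]
  is_mito <- startsWith(toupper(gene_names2), toupper(mito_prefix))
  totals <- Matrix::rowSums(v2)
  mito_pct <- if (any(is_mito)) {
    100 * Matrix::rowSums(v2[, is_mito, drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, nrow(v2))
  }
  keep_mito <- mito_pct <= max_mito_pct
  if (!any(keep_mito)) {
    stop("empty after QC: no cell passed the mitochondrial filter")
  }
  v3 <- v2[keep_mito, , drop = FALSE]

  out <- count_matrix(v3, cell_ids = m$cell_ids[keep_cell][keep_mito],
                      gene_names = gene_names2)
  report <- structure(list(
    n_cells_in = n_cells_in, n_cells_out = nrow(v3),
    n_genes_in = n_genes_in, n_genes_out = ncol(v3),
    n_genes_dropped_support = sum(!keep_gene),
    n_cells_dropped_genes = sum(!keep_cell),
    n_cells_dropped_mito = sum(!keep_mito),
    genes_per_cell = as.numeric(genes_per_cell),
    total_counts = as.numeric(Matrix::rowSums(v1)),
    mito_pct_surviving_cells = as.numeric(mito_pct),
    thresholds = list(min_cells_per_gene = min_cells_per_gene,
                      min_genes_per_cell = min_genes_per_cell,
                      max_mito_pct = max_mito_pct,
                      mito_prefix = mito_prefix)
  ), class = "QCReport")
  list(counts = out, report = report)
}

#' Counts-per-million normalization with log scaling
#'
#' Scales each cell so its counts sum to one million
#' (`CPM = count / totalReads * 1e6`), then applies the natural-log
#' transform `log(1 + CPM)`.
#'
#' @param m a [count_matrix()] object; every cell must have total count > 0
#'   (guaranteed after [qc_filter()]).
#' @return An [expression_matrix()] at stage `"normalized"`.
#' @export
cpm_lognormalize <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  totals <- Matrix::rowSums(m$values)
  if (any(totals <= 0)) {
    stop("zero-total cell found; run qc_filter() first")
  }
  cpm <- as.matrix(m$values / totals * 1e6)
  expression_matrix(log1p(cpm), m$cell_ids, m$gene_names,
                    stage = "normalized")
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Per-gene mean and dispersion (variance / mean) are computed on the
#' log-normalized values. Genes are binned by mean into `n_bins`
#' equal-occupancy bins and dispersions are z-scored within each bin
#' (population standard deviation); bins holding a single gene use a
#' standard deviation of 1. Selected genes satisfy
#' `min_mean <= mean <= max_mean` and normalized dispersion `>= min_disp`.
#' Genes with zero mean are excluded before binning. The mean window
#' defaults are on the log1p-CPM scale and exclude near-silent and
#' saturated genes.
#'
#' @param e an [expression_matrix()] at stage `"normalized"`.
#' @param n_bins number of equal-occupancy mean bins (default 20).
#' @param min_disp minimum z-scored dispersion (default 0.5).
#' @param min_mean,max_mean mean-expression window on log1p-CPM values.
#' @return A list with `expr` (the matrix restricted to selected genes, stage
#'   `"hvg"`) and `hvg_mask`, a named logical over all input genes.
#' @export
select_hvgs <- function(e, n_bins = 20L, min_disp = 0.5,
                        min_mean = 0.1, max_mean = 12.0) {
  stopifnot(inherits(e, "ExpressionMatrix"))
  .check_stage(e, "normalized")
  x <- e$values
  mu <- colMeans(x)
  vr <- .colvar_pop(x)
  disp <- ifelse(mu > 0, vr / mu, NA_real_)

  idx <- which(mu > 0)
  if (length(idx) == 0L) stop("no gene selected: all genes have zero mean")
  n_inc <- length(idx)
  nb <- max(1L, min(as.integer(n_bins), n_inc))
  # equal-occupancy bins on the rank of the mean
  r <- rank(mu[idx], ties.method = "first")
  bin <- pmin(nb, 1L + ((r - 1L) * nb) %/% n_inc)

  z <- rep(NA_real_, ncol(x))
  for (b in seq_len(nb)) {
    g <- idx[bin == b]
    if (length(g) == 0L) next
    mb <- mean(disp[g])
    sb <- sqrt(mean((disp[g] - mb)^2))
    if (length(g) < 2L || sb == 0) sb <- 1
    z[g] <- (disp[g] - mb) / sb
  }
  mask <- !is.na(z) & z >= min_disp & mu >= min_mean & mu <= max_mean
  names(mask) <- e$gene_names
  if (!any(mask)) stop("no gene selected: HVG criteria left an empty set")
  expr <- expression_matrix(x[, mask, drop = FALSE], e$cell_ids,
                            e$gene_names[mask], stage = "hvg")
  list(expr = expr, hvg_mask = mask, normalized_dispersion = z,
       gene_mean = mu)
}

# population-variance of each column
.colvar_pop <- function(x) {
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}

#' Regress out per-cell covariates
#'
#' Fits, per gene, an ordinary least squares model of expression on an
#' intercept plus the given covariates (typically total counts per cell and
#' mitochondrial percentage) and replaces values by the residuals, removing
#' these technical sources of variation. Constant or collinear covariate
#' columns are dropped with a warning.
#'
#' @param e an [expression_matrix()] at stage `"hvg"` (or `"normalized"`).
#' @param covariates numeric matrix or data.frame, one row per cell.
#' @return An [expression_matrix()] at stage `"regressed"`.
#' @export
regress_out <- function(e, covariates) {
  stopifnot(inherits(e, "ExpressionMatrix"))
  .check_stage(e, c("normalized", "hvg"))
  cv <- as.matrix(covariates)
  stopifnot(nrow(cv) == nrow(e$values))
  design <- cbind(`(Intercept)` = 1, cv)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    warning(sprintf("dropping %d redundant covariate column(s)",
                    ncol(design) - qrd$rank))
    design <- design[, sort(keep), drop = FALSE]
    qrd <- qr(design)
  }
  resid <- qr.resid(qrd, e$values)
  expression_matrix(resid, e$cell_ids, e$gene_names, stage = "regressed")
}

#' Scale genes to unit variance
#'
#' Centers each gene to mean zero, divides by its population standard
#' deviation, and clips values to `[-clip_max, clip_max]` so extreme cells
#' cannot dominate the embedding. Zero-variance genes map to zero.
#'
#' @param e an [expression_matrix()] at stage `"regressed"` (or earlier; the
#'   stage check only forbids re-scaling).
#' @param clip_max clipping bound (default 10).
#' @return An [expression_matrix()] at stage `"scaled"`.
#' @export
scale_unit_variance <- function(e, clip_max = 10.0) {
  stopifnot(inherits(e, "ExpressionMatrix"))
  .check_stage(e, c("normalized", "hvg", "regressed"))
  x <- e$values
  mu <- colMeans(x)
  sd_pop <- sqrt(.colvar_pop(x))
  xc <- sweep(x, 2L, mu)
  nz <- sd_pop > 0
  xc[, nz] <- sweep(xc[, nz, drop = FALSE], 2L, sd_pop[nz], "/")
  xc[, !nz] <- 0
  xc[xc > clip_max] <- clip_max
  xc[xc < -clip_max] <- -clip_max
  expression_matrix(xc, e$cell_ids, e$gene_names, stage = "scaled")
}
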