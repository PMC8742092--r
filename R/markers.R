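#' Rank marker genes per cluster by one-vs-rest Wilcoxon tests
#'
#' For every cluster and gene, a two-sided Wilcoxon rank-sum test compares
#' the cells in the cluster against all other cells, using the normal
#' approximation with tie correction (ranks computed once per gene over all
#' cells). P-values are Benjamini-Hochberg adjusted across genes within each
#' cluster. Expression should be the log-normalized matrix (pre-scaling) so
#' the reported log fold change, `mean(in) - mean(out)` on log values, stays
#' interpretable. Within a cluster, rows are sorted by ascending p-value,
#' ties broken by descending `|z|`, then gene name; the top `n_top` rows per
#' cluster are kept. Clusters of fewer than 2 cells are skipped with a
#' warning.
#'
#' @param e an [expression_matrix()] (any stage; log-normalized recommended)
#'   or a plain cells x genes matrix with column names.
#' @param labels cluster labels, one per cell; at least 2 clusters of
#'   size >= 2.
#' @param n_top markers kept per cluster (default 20).
#' @return A `MarkerTable` data.frame with columns `cluster`, `gene_name`,
#'   `rank`, `z_statistic`, `p_value`, `adjusted_p`, `log_fold_change`.
#' @export
rank_markers <- function(e, labels, n_top = 20L) {
  X <- if (inherits(e, "ExpressionMatrix")) e$values else as.matrix(e)
  if (is.null(colnames(X))) colnames(X) <- paste0("G", seq_len(ncol(X)))
  n <- nrow(X); G <- ncol(X)
  stopifnot(length(labels) == n)
  labf <- factor(labels)
  if (nlevels(labf) < 2L) stop("parameter error: need >= 2 clusters")

  R <- apply(X, 2L, rank)               # mid-ranks per gene over all cells
  tie_term <- apply(X, 2L, function(x) {
    tt <- tabulate(match(x, unique(x)))
    sum(tt^3 - tt)
  })

  out <- list()
  for (cl in levels(labf)) {
    inc <- labf == cl
    n1 <- sum(inc); n2 <- n - n1
    if (n1 < 2L) {
      warning(sprintf("cluster '%s' has fewer than 2 cells; skipped", cl))
      next
    }
    W <- colSums(R[inc, , drop = FALSE])          # rank sum of in-group
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(sigma2 > 0, (W - mu) / sqrt(sigma2), 0)
    p <- pmin(1, 2 * pnorm(-abs(z)))
    padj <- p.adjust(p, method = "BH")
    lfc <- colMeans(X[inc, , drop = FALSE]) - colMeans(X[!inc, , drop = FALSE])
    o <- order(p, -abs(z), colnames(X))
    keep <- o[seq_len(min(n_top, G))]
    out[[cl]] <- data.frame(
      cluster = cl, gene_name = colnames(X)[keep],
      rank = seq_along(keep), z_statistic = z[keep], p_value = p[keep],
      adjusted_p = padj[keep], log_fold_change = lfc[keep],
      rank_sum = W[keep],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(out) == 0L) stop("no cluster of size >= 2")
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  class(tbl) <- c("MarkerTable", "data.frame")
  tbl
}

#' Export ranked gene lists for external enrichment tools
#'
#' Writes, per cluster, either a ranked `.rnk` file (gene name and signed z
#' statistic, ordered by descending z) or a plain `.grp` gene list, the two
#' plain-text formats consumed by standard gene-set enrichment tools. Gene
#' names pass through verbatim.
#'
#' @param t a `MarkerTable` from [rank_markers()].
#' @param path output directory (created if needed).
#' @param format `"rnk"` or `"grp"`.
#' @return Invisibly, the paths written.
#' @export
export_gene_lists <- function(t, path, format = c("rnk", "grp")) {
  format <- match.arg(format)
  stopifnot(inherits(t, "data.frame"), nrow(t) > 0)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("I/O error: cannot create directory %s", path))
  }
  files <- character(0)
  for (cl in unique(t$cluster)) {
    sub <- t[t$cluster == cl, , drop = FALSE]
    f <- file.path(path, sprintf("cluster_%s.%s", cl, format))
    if (format == "rnk") {
      sub <- sub[order(-sub$z_statistic), , drop = FALSE]
      write.table(sub[, c("gene_name", "z_statistic")], f, sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else {
      writeLines(sub$gene_name, f)
    }
    files <- c(files, f)
  }
  invisible(files)
}
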