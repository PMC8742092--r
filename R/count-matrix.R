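#' Construct a cell-by-gene count matrix
#'
#' Container for raw (and QC-filtered) scRNA-seq counts. Rows are cells,
#' columns are genes; values must be non-negative integers. The matrix is
#' stored sparse (`dgCMatrix`).
#'
#' @param values numeric matrix or sparse Matrix, cells x genes, non-negative
#'   integers.
#' @param cell_ids character vector of unique cell barcodes (length = rows).
#' @param gene_names character vector of unique gene names (length = cols).
#' @return An object of class `CountMatrix` with elements `values`
#'   (`dgCMatrix`), `cell_ids`, `gene_names`.
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_names = colnames(values)) {
  if (is.null(cell_ids) || is.null(gene_names)) {
    stop("count_matrix() needs cell_ids and gene_names")
  }
  vals <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(vals) == 0L || ncol(vals) == 0L) {
    stop("validation error: count matrix has zero cells or zero genes")
  }
  if (length(cell_ids) != nrow(vals)) {
    stop("validation error: length(cell_ids) != number of rows (cells)")
  }
  if (length(gene_names) != ncol(vals)) {
    stop("validation error: length(gene_names) != number of columns (genes)")
  }
  x <- vals@x
  bad <- which(x < 0 | x != round(x) | !is.finite(x))
  if (length(bad) > 0L) {
    coord <- .first_coord(vals, bad[1L])
    stop(sprintf(
      "validation error: non-integer or negative entry %g at cell %d, gene %d",
      x[bad[1L]], coord[1L], coord[2L]
    ))
  }
  if (anyDuplicated(cell_ids)) {
    stop("validation error: duplicate cell_ids")
  }
  if (anyDuplicated(gene_names)) {
    stop("validation error: duplicate gene_names")
  }
  dimnames(vals) <- list(cell_ids, gene_names)
  structure(
    list(values = vals, cell_ids = as.character(cell_ids),
         gene_names = as.character(gene_names)),
    class = "CountMatrix"
  )
}

# row/col coordinate of the k-th stored element of a dgCMatrix;
# column j holds stored elements (p[j]+1)..p[j+1]
.first_coord <- function(m, k) {
  j <- max(which(m@p < k))
  i <- m@i[k] + 1L
  c(i, j)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf(
    "CountMatrix: %d cells x %d genes, %d non-zero entries, total count %s\n",
    nrow(x$values), ncol(x$values), length(x$values@x),
    format(sum(x$values), big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Read a count matrix from disk
#'
#' Accepts either a 10x-style Matrix-Market triplet (a directory containing
#' `matrix.mtx`, `barcodes.tsv`, `features.tsv`, with the matrix stored genes
#' x cells and transposed on load) or a dense CSV/TSV with a header row of
#' gene names and a first column of cell ids (cells x genes). Orientation of
#' the returned object is always cells x genes. Duplicate gene names or
#' barcodes are made unique by appending `.1`, `.2`, ... in file order.
#'
#' @param path path to a directory (MTX triplet), a `.mtx` file, or a dense
#'   `.csv` / `.tsv` file.
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: no such file or directory: %s", path))
  }
  if (dir.exists(path)) {
    return(.read_counts_mtx(file.path(path, "matrix.mtx"),
                            file.path(path, "barcodes.tsv"),
                            file.path(path, "features.tsv")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    d <- dirname(path)
    return(.read_counts_mtx(path, file.path(d, "barcodes.tsv"),
                            file.path(d, "features.tsv")))
  }
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                   check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("validation error: empty matrix (0 cells or 0 genes) in ", path)
  }
  vals <- as.matrix(df)
  storage.mode(vals) <- "double"
  count_matrix(Matrix(vals, sparse = TRUE),
               cell_ids = make.unique(rownames(df)),
               gene_names = make.unique(colnames(df)))
}

.read_counts_mtx <- function(mtx, barcodes, features) {
  for (f in c(mtx, barcodes, features)) {
    if (!file.exists(f)) stop(sprintf("I/O error: no such file: %s", f))
  }
  m <- readMM(mtx)                       # genes x cells on disk
  bc <- readLines(barcodes)
  ft <- read.delim(features, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  # features.tsv: id [, name, ...]; the name column is used when present
  gene <- if (ncol(ft) >= 2L) ft[[2L]] else ft[[1L]]
  if (nrow(m) != length(gene)) {
    stop(sprintf(
      "validation error: features.tsv has %d entries but matrix has %d genes",
      length(gene), nrow(m)
    ))
  }
  if (ncol(m) != length(bc)) {
    stop(sprintf(
      "validation error: barcodes.tsv has %d entries but matrix has %d cells",
      length(bc), ncol(m)
    ))
  }
  count_matrix(Matrix::t(m), cell_ids = make.unique(bc),
               gene_names = make.unique(gene))
}

#' Write a count matrix to disk
#'
#' `mtx` writes a 10x-style triplet (`matrix.mtx` genes x cells +
#' `barcodes.tsv` + `features.tsv`) into the directory `path`; `csv` writes a
#' dense cells x genes table with header and index. Both round-trip
#' bit-exactly through [read_counts()] for integer data.
#'
#' @param m a [count_matrix()] object.
#' @param path output directory (`mtx`) or file path (`csv`).
#' @param format `"mtx"` or `"csv"`.
#' @export
write_counts <- function(m, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "CountMatrix"))
  if (format == "mtx") {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop(sprintf("I/O error: cannot create directory %s", path))
    }
    writeMM(Matrix::t(m$values), file.path(path, "matrix.mtx"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    write.table(
      data.frame(id = m$gene_names, name = m$gene_names),
      file.path(path, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  } else {
    dense <- as.matrix(m$values)
    df <- as.data.frame(dense)
    tryCatch(
      write.table(cbind(cell_id = m$cell_ids, df), path, sep = ",",
                  quote = FALSE, row.names = FALSE),
      error = function(e) stop(sprintf("I/O error writing %s: %s", path,
                                       conditionMessage(e)))
    )
  }
  invisible(NULL)
}
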