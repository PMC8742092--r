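#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults. The QC
#' thresholds (genes expressed in fewer than 3 cells, cells with fewer than
#' 200 expressed genes) and the sweep ranges (neighbors 8..24, clusters
#' 4..14) follow the published protocol; the remaining defaults are this
#' package's documented choices.
#'
#' @return A named list of class `RunConfig`.
#' @export
default_config <- function() {
  structure(list(
    # qc
    min_cells_per_gene = 3L,
    min_genes_per_cell = 200L,
    max_mito_pct       = 5.0,
    mito_prefix        = "MT-",
    # hvg
    n_bins   = 20L,
    min_disp = 0.5,
    min_mean = 0.1,
    max_mean = 12.0,
    # covariate regression + scaling
    regress  = TRUE,
    clip_max = 10.0,
    # embedding; dims_stage1 enables an optional two-pass reduction
    # (first to dims_stage1, then to dims)
    method      = "mlle",
    neighbors   = 12L,
    dims        = 3L,
    dims_stage1 = NA_integer_,
    tolerance   = 1e-6,
    # ica
    use_ica       = TRUE,
    ica_dims      = 2L,
    cluster_space = "ica",
    # clustering
    k        = NA_integer_,   # NA -> choose by sweep
    n_init   = 10L,
    max_iter = 300L,
    # sweep grids
    t_grid   = 8:24,
    k_grid   = 4:14,
    m_grid   = 3L,
    tol_grid = 10^seq(-12, -3),
    selection_rule = "sh_primary",
    # markers
    n_top_markers = 20L,
    seed = 0L
  ), class = "RunConfig")
}

#' Load a run configuration from a key/value text file
#'
#' The file is plain YAML key/value text. Omitted keys take the documented
#' defaults of [default_config()]; unknown keys are rejected by name.
#'
#' @param path path to the config file. An empty file yields all defaults.
#' @return A `RunConfig` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: no such file: %s", path))
  }
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("validation error: unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    tmpl <- cfg[[k]]
    v <- user[[k]]
    cfg[[k]] <- if (is.integer(tmpl)) as.integer(v)
                else if (is.numeric(tmpl)) as.numeric(v)
                else if (is.logical(tmpl)) as.logical(v)
                else as.character(v)
  }
  cfg
}

#' Save a run configuration
#'
#' @param cfg a `RunConfig` list.
#' @param path output file path. Round-trips through [load_config()].
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig") || is.list(cfg))
  yaml::write_yaml(unclass(cfg), path)
  invisible(NULL)
}
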