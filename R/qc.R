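#' Quality-control thresholds
#'
#' Defaults follow the standard droplet QC regime used throughout the
#' pipeline: first-round cell filters (minimum UMIs and detected genes,
#' maximum hemoglobin counts and mitochondrial fraction), a stricter
#' second-round refilter applied to neuronal cells only, and the gene filter
#' (a gene is retained when at least `gene_min_cells` cells carry at least
#' `gene_min_count` of its counts). All exclusion inequalities are strict,
#' so boundary values are kept.
#'
#' @param min_counts minimum UMIs per cell (cells with fewer are excluded).
#' @param min_genes minimum detected genes per cell.
#' @param max_hemoglobin maximum hemoglobin counts per cell (more excludes).
#' @param max_mito_fraction maximum mitochondrial count fraction.
#' @param neuronal_min_counts,neuronal_min_genes second-round thresholds for
#'   neuronal cells.
#' @param gene_min_count,gene_min_cells gene retention rule.
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_counts = 2000, min_genes = 1000,
                          max_hemoglobin = 50, max_mito_fraction = 0.15,
                          neuronal_min_counts = 3500,
                          neuronal_min_genes = 2200,
                          gene_min_count = 3, gene_min_cells = 3) {
  t <- list(min_counts = min_counts, min_genes = min_genes,
            max_hemoglobin = max_hemoglobin,
            max_mito_fraction = max_mito_fraction,
            neuronal_min_counts = neuronal_min_counts,
            neuronal_min_genes = neuronal_min_genes,
            gene_min_count = gene_min_count, gene_min_cells = gene_min_cells)
  if (any(unlist(t) < 0)) stopf("thresholds must be non-negative")
  if (neuronal_min_counts < min_counts || neuronal_min_genes < min_genes) {
    stopf("neuronal thresholds must not be looser than first-round thresholds")
  }
  structure(t, class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell: total UMIs, number of detected genes (nonzero
#' count), summed counts over hemoglobin-flagged genes, and the
#' mitochondrial count fraction (0 for an all-zero cell).
#'
#' @param x a `count_matrix`; genes must be flagged with [annotate_genes()]
#'   before hemoglobin / mitochondrial metrics are meaningful.
#' @return A data.frame with columns `cell_id`, `total_counts`, `n_genes`,
#'   `hemoglobin_counts`, `mito_fraction`.
#' @export
compute_cell_qc <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (!all(c("mito", "hemoglobin") %in% colnames(x$gene_meta))) {
    stopf("gene flags missing; run annotate_genes() first")
  }
  total <- Matrix::rowSums(x$counts)
  ngenes <- Matrix::rowSums(x$counts > 0)
  hgb <- Matrix::rowSums(x$counts[, gene_flag(x, "hemoglobin"), drop = FALSE])
  mito <- Matrix::rowSums(x$counts[, gene_flag(x, "mito"), drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 0)
  data.frame(cell_id = x$cell_ids, total_counts = as.numeric(total),
             n_genes = as.integer(ngenes),
             hemoglobin_counts = as.numeric(hgb),
             mito_fraction = mito_frac, row.names = NULL)
}

#' First-round cell filter
#'
#' A cell is kept iff `total_counts >= min_counts` and `n_genes >= min_genes`
#' and `hemoglobin_counts <= max_hemoglobin` and
#' `mito_fraction <= max_mito_fraction`. Exclusions are strict inequalities,
#' so a cell sitting exactly on every boundary is kept.
#'
#' @param metrics output of [compute_cell_qc()].
#' @param t a [qc_thresholds()] object.
#' @return Integer indices of kept cells.
#' @export
filter_cells <- function(metrics, t = qc_thresholds()) {
  keep <- metrics$total_counts >= t$min_counts &
    metrics$n_genes >= t$min_genes &
    metrics$hemoglobin_counts <= t$max_hemoglobin &
    metrics$mito_fraction <= t$max_mito_fraction
  which(keep)
}

#' Gene filter
#'
#' Retains genes having at least `gene_min_count` counts in at least
#' `gene_min_cells` cells.
#'
#' @param x a `count_matrix`.
#' @param t a [qc_thresholds()] object.
#' @return Integer indices of kept genes.
#' @export
filter_genes <- function(x, t = qc_thresholds()) {
  stopifnot(inherits(x, "count_matrix"))
  n_ok <- Matrix::colSums(x$counts >= t$gene_min_count)
  unname(which(n_ok >= t$gene_min_cells))
}

#' Second-round neuronal cell refilter
#'
#' Neuronal cells are refiltered with stricter depth thresholds: cells with
#' fewer than `neuronal_min_counts` UMIs or fewer than `neuronal_min_genes`
#' detected genes are excluded (strictly), boundary values kept.
#'
#' @param x a `count_matrix`.
#' @param neuronal_cells integer indices (into `x`'s cells) of the neuronal
#'   subset.
#' @param t a [qc_thresholds()] object.
#' @return Integer indices (into `x`'s cells) of kept neuronal cells.
#' @export
neuronal_refilter <- function(x, neuronal_cells, t = qc_thresholds()) {
  stopifnot(inherits(x, "count_matrix"))
  if (!length(neuronal_cells)) return(integer(0))
  if (any(neuronal_cells < 1 | neuronal_cells > n_cells(x))) {
    stopf("neuronal_cells out of range")
  }
  sub <- x$counts[neuronal_cells, , drop = FALSE]
  total <- Matrix::rowSums(sub)
  ngenes <- Matrix::rowSums(sub > 0)
  neuronal_cells[total >= t$neuronal_min_counts &
                   ngenes >= t$neuronal_min_genes]
}
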