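#' Construct a cell-by-gene count matrix object
#'
#' `count_matrix()` is the pipeline's entry container: a sparse matrix of
#' non-negative integer UMI counts with cells as rows and genes as columns,
#' carrying per-cell sample metadata (sample, sex, chemistry batch) and
#' per-gene category flags (mitochondrial, ribosomal, hemoglobin, cell cycle,
#' excluded immediate-early).
#'
#' @param counts matrix or sparse Matrix of non-negative integers,
#'   cells x genes.
#' @param cell_ids character vector of unique cell barcodes (rows).
#' @param gene_ids character vector of unique gene symbols (columns).
#' @param cell_meta data.frame with one row per cell (columns such as
#'   `sample`, `sex`, `batch`), or `NULL` for empty metadata.
#' @param gene_meta data.frame of logical per-gene category flags, or `NULL`
#'   (flags are filled in by [annotate_genes()]).
#'
#' @return An object of class `"count_matrix"` with elements `counts`
#'   (a `dgCMatrix`), `cell_ids`, `gene_ids`, `cell_meta`, `gene_meta`.
#' @export
count_matrix <- function(counts, cell_ids, gene_ids, cell_meta = NULL,
                         gene_meta = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts * 1, "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(cell_ids)) {
    stopf("counts has %d rows but %d cell ids were given",
          nrow(counts), length(cell_ids))
  }
  if (ncol(counts) != length(gene_ids)) {
    stopf("counts has %d columns but %d gene ids were given",
          ncol(counts), length(gene_ids))
  }
  if (anyDuplicated(cell_ids)) stopf("cell ids are not unique")
  if (anyDuplicated(gene_ids)) stopf("gene ids are not unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x)))) {
    stopf("counts must be non-negative integers")
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids)) {
      stopf("cell_meta has %d rows for %d cells", nrow(cell_meta),
            length(cell_ids))
    }
    rownames(cell_meta) <- cell_ids
  }
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(row.names = gene_ids)
  } else {
    gene_meta <- as.data.frame(gene_meta)
    if (nrow(gene_meta) != length(gene_ids)) {
      stopf("gene_meta has %d rows for %d genes", nrow(gene_meta),
            length(gene_ids))
    }
    rownames(gene_meta) <- gene_ids
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(
    list(counts = counts, cell_ids = as.character(cell_ids),
         gene_ids = as.character(gene_ids), cell_meta = cell_meta,
         gene_meta = gene_meta),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%d nonzero entries)\n",
              n_cells(x), n_genes(x), length(x$counts@x)))
  if (ncol(x$cell_meta)) {
    cat("  cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  }
  if (ncol(x$gene_meta)) {
    cat("  gene flags:", paste(colnames(x$gene_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells / genes in a count matrix
#' @param x a `count_matrix`.
#' @return integer count.
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$counts)

#' Subset a count matrix by cells and/or genes
#'
#' @param x a `count_matrix`.
#' @param cells,genes index vectors (integer, logical or character) selecting
#'   rows / columns; `NULL` keeps all.
#' @return a `count_matrix` restricted to the selection, metadata aligned.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  cells <- cells %||% seq_len(n_cells(x))
  genes <- genes %||% seq_len(n_genes(x))
  if (is.character(cells)) cells <- match(cells, x$cell_ids)
  if (is.character(genes)) genes <- match(genes, x$gene_ids)
  count_matrix(x$counts[cells, genes, drop = FALSE],
               x$cell_ids[cells], x$gene_ids[genes],
               x$cell_meta[cells, , drop = FALSE],
               x$gene_meta[genes, , drop = FALSE])
}

# Logical flag column helper: missing column means "no gene flagged".
gene_flag <- function(x, flag) {
  if (flag %in% colnames(x$gene_meta)) {
    x$gene_meta[[flag]]
  } else {
    rep(FALSE, n_genes(x))
  }
}
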