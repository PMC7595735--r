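#' Read a 10x-style MatrixMarket triplet into a count matrix
#'
#' Reads a MatrixMarket coordinate integer file together with its barcode and
#' feature TSV sidecars. On-disk orientation is accepted either way
#' (genes x cells, as the 10x toolchain writes, or cells x genes) and is
#' inferred from the sidecar line counts; the returned object is always
#' cells x genes. A square matrix with equally long sidecars is resolved as
#' genes x cells (the 10x convention).
#'
#' @param matrix_path path to the `.mtx` coordinate file.
#' @param barcodes_path path to `barcodes.tsv` (one barcode per line).
#' @param features_path path to `features.tsv` (gene id, optionally
#'   tab-followed by a gene symbol; the symbol column is used as the gene id
#'   when present).
#'
#' @return A [count_matrix()] with empty metadata slots.
#' @export
read_counts_triplet <- function(matrix_path, barcodes_path, features_path) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  feat <- read.table(features_path, sep = "\t", header = FALSE,
                     colClasses = "character", quote = "")
  gene_ids <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  nb <- length(barcodes)
  ng <- length(gene_ids)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    stopf("matrix is %d x %d but sidecars declare %d barcodes and %d features",
          nrow(m), ncol(m), nb, ng)
  }
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != floor(x)))) {
    stopf("matrix entries must be non-negative integers")
  }
  count_matrix(m, barcodes, gene_ids)
}

#' Write a count matrix as a 10x-style MatrixMarket triplet
#'
#' Emits `matrix.mtx` (genes x cells, MatrixMarket coordinate integer),
#' `barcodes.tsv` and `features.tsv` into `out_dir`. Reading the files back
#' with [read_counts_triplet()] reproduces the counts, cell ids and gene ids
#' exactly (metadata is not serialized here; see [run_pipeline()] artifacts).
#'
#' @param x a `count_matrix` with at least one cell.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the paths of the three files written.
#' @export
write_counts_triplet <- function(x, out_dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (n_cells(x) == 0) stopf("refusing to write a cohort with zero cells")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  # genes x cells on disk; written directly because Matrix::writeMM
  # downgrades numerically symmetric or all-one matrices to
  # "pattern"/"symmetric" layouts, which is not the 10x triplet contract
  m <- as(as(Matrix::t(x$counts), "generalMatrix"), "TsparseMatrix")
  ord <- order(m@j, m@i)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(m@x)),
               sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L,
                       as.integer(m@x[ord]))),
             paths[1])
  writeLines(x$cell_ids, paths[2])
  writeLines(paste(x$gene_ids, x$gene_ids, sep = "\t"), paths[3])
  invisible(paths)
}

#' Concatenate per-library count matrices
#'
#' Stacks the cells of several libraries that share one reference gene list
#' into a single aggregate, prefixing cell barcodes with the sample label
#' (from `cell_meta$sample` or the list name) when needed to keep them
#' unique. Per-cell metadata columns are preserved (union of columns, `NA`
#' where absent); gene flags are taken from the first input.
#'
#' @param matrices list of `count_matrix` objects with identical `gene_ids`.
#' @return A single `count_matrix` with `sum(cells)` rows.
#' @export
concatenate_samples <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  g <- matrices[[1]]$gene_ids
  for (i in seq_along(matrices)) {
    if (!identical(matrices[[i]]$gene_ids, g)) {
      stopf("input %d has a different gene list; all libraries must share one reference", i)
    }
  }
  labels <- names(matrices) %||% as.character(seq_along(matrices))
  if (is.null(names(matrices))) {
    labels <- vapply(seq_along(matrices), function(i) {
      s <- unique(matrices[[i]]$cell_meta$sample)
      if (length(s) == 1 && !is.na(s)) as.character(s) else as.character(i)
    }, character(1))
  }
  ids <- unlist(lapply(matrices, function(m) m$cell_ids))
  if (anyDuplicated(ids)) {
    ids <- unlist(lapply(seq_along(matrices), function(i) {
      paste(labels[i], matrices[[i]]$cell_ids, sep = "_")
    }))
  }
  cols <- unique(unlist(lapply(matrices, function(m) colnames(m$cell_meta))))
  meta <- if (length(cols)) {
    do.call(rbind, lapply(matrices, function(m) {
      cm <- m$cell_meta
      for (cl in setdiff(cols, colnames(cm))) cm[[cl]] <- NA
      cm[, cols, drop = FALSE]
    }))
  } else {
    NULL
  }
  counts <- do.call(rbind, lapply(matrices, function(m) m$counts))
  count_matrix(counts, ids, g, meta, matrices[[1]]$gene_meta)
}
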