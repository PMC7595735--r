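#' Depth-normalize counts to a log2 scale
#'
#' Each cell's counts are divided by the cell's total, multiplied by the
#' median total across all cells, and log2-transformed with a pseudocount of
#' one: `value(c, g) = log2(1 + counts(c, g) / T_c * median(T))`. Before the
#' log, every cell's scaled total therefore equals the median total exactly
#' (depth conservation).
#'
#' @param x a `count_matrix` with no all-zero cells (guaranteed after QC).
#' @return An object of class `"normalized_matrix"`: `values` (dense
#'   cells x genes matrix, log2 scale), `size_factors` (per-cell totals),
#'   `scale_target` (median total), plus the ids and metadata of `x`.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- as.numeric(Matrix::rowSums(x$counts))
  if (any(totals == 0)) {
    stopf("cell '%s' has zero total counts; filter cells before normalizing",
          x$cell_ids[which(totals == 0)[1]])
  }
  target <- median(totals)
  values <- as.matrix(x$counts) * (target / totals)
  values <- log2(1 + values)
  dimnames(values) <- list(x$cell_ids, x$gene_ids)
  structure(
    list(values = values, size_factors = totals, scale_target = target,
         cell_ids = x$cell_ids, gene_ids = x$gene_ids,
         cell_meta = x$cell_meta, gene_meta = x$gene_meta),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes (log2 scale, target %.1f)\n",
              nrow(x$values), ncol(x$values), x$scale_target))
  invisible(x)
}

#' Select highly variable genes by dispersion
#'
#' Per-gene dispersion is variance over mean of the normalized expression.
#' Genes are grouped into `n_bins` equal-frequency bins by mean, and the
#' dispersion is standardized within each bin (a z-score), so that highly
#' variable genes are those unusually dispersed for their expression level.
#' Genes flagged mitochondrial, ribosomal, hemoglobin, cell-cycle, or
#' excluded immediate-early are removed from candidacy (they stay in the
#' matrix for all downstream scoring). The top `n_hvg` eligible genes by
#' normalized dispersion are selected; ties are broken by higher raw
#' dispersion, then lexicographic gene id.
#'
#' @param norm a `normalized_matrix` carrying gene flags.
#' @param n_hvg number of genes to select.
#' @param n_bins equal-frequency mean bins for standardization.
#' @param method `"binned"` (default, bin-standardized dispersion) or
#'   `"raw"` (rank by raw dispersion directly).
#' @return An object of class `"hvg_selection"`: `table` (per-gene data.frame
#'   with mean, dispersion, normalized_dispersion, excluded, selected) and
#'   `selected` (character vector of gene ids, in rank order).
#' @export
select_hvgs <- function(norm, n_hvg = 1500, n_bins = 20,
                        method = c("binned", "raw")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  method <- match.arg(method)
  v <- norm$values
  mu <- colMeans(v)
  vr <- apply(v, 2, var)
  disp <- ifelse(mu > 0, vr / mu, 0)

  norm_disp <- disp
  eligible_mean <- mu > 0
  if (method == "binned") {
    if (sum(eligible_mean) < n_bins) {
      stopf("need at least %d genes with nonzero mean for %d bins",
            n_bins, n_bins)
    }
    bins <- rep(NA_integer_, length(mu))
    # equal-frequency bins over genes with nonzero mean, ties kept together
    r <- rank(mu[eligible_mean], ties.method = "first")
    bins[eligible_mean] <- ceiling(r / (sum(eligible_mean) / n_bins))
    norm_disp <- rep(0, length(mu))
    for (b in unique(bins[!is.na(bins)])) {
      idx <- which(bins == b)
      m <- mean(disp[idx])
      s <- if (length(idx) > 1) stats::sd(disp[idx]) else 0
      norm_disp[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
    }
  }

  flags <- norm$gene_meta
  excluded <- rep(FALSE, length(mu))
  for (f in c("mito", "ribo", "hemoglobin", "cell_cycle", "iexcl")) {
    if (f %in% colnames(flags)) excluded <- excluded | flags[[f]]
  }

  eligible <- which(!excluded & eligible_mean)
  ord <- eligible[order(-norm_disp[eligible], -disp[eligible],
                        norm$gene_ids[eligible])]
  if (length(ord) < n_hvg) {
    warnf("only %d eligible genes for n_hvg = %d; returning all",
          length(ord), n_hvg)
  }
  sel_idx <- head(ord, n_hvg)
  selected <- rep(FALSE, length(mu))
  selected[sel_idx] <- TRUE

  structure(
    list(table = data.frame(gene = norm$gene_ids, mean = mu,
                            dispersion = disp,
                            normalized_dispersion = norm_disp,
                            excluded = excluded, selected = selected,
                            row.names = NULL),
         selected = norm$gene_ids[sel_idx],
         n_hvg = n_hvg, n_bins = n_bins, method = method),
    class = "hvg_selection")
}
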