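#' Co-expression percentage for counted cells
#'
#' Percentage of probe-positive cells among all counted cells in an imaging
#' field (the quantity reported beside FISH pie charts), rounded half-up to
#' one decimal.
#'
#' @param positive_count non-negative integer, cells positive for the probe.
#' @param total_count positive integer, all counted cells.
#' @return Percentage in \[0, 100\] with one decimal.
#' @export
#' @examples
#' coexpression_percentage(176, 197)  # 89.3
coexpression_percentage <- function(positive_count, total_count) {
  if (total_count <= 0) stopf("total_count must be positive")
  if (positive_count < 0 || positive_count > total_count) {
    stopf("positive_count must be between 0 and total_count")
  }
  round_half_up(100 * positive_count / total_count, 1)
}

#' Median sequencing depth of a cohort
#'
#' Median UMIs per cell and median detected genes per cell. An even number
#' of cells uses the midpoint convention.
#'
#' @param x a `count_matrix` with at least one cell.
#' @return Named numeric vector `c(median_umis, median_genes)`.
#' @export
summarize_depth <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (n_cells(x) == 0) stopf("empty matrix")
  totals <- as.numeric(Matrix::rowSums(x$counts))
  ngenes <- as.numeric(Matrix::rowSums(x$counts > 0))
  c(median_umis = median(totals), median_genes = median(ngenes))
}
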