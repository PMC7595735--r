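#' Gene category annotations for QC and HVG exclusion
#'
#' Bundles the gene lists the pipeline needs: prefix rules for mitochondrial
#' and ribosomal genes, and explicit symbol lists for hemoglobin, cell-cycle,
#' and excluded immediate-early genes (plus Xist). Matching is case-sensitive
#' on mouse-style symbols.
#'
#' The default cell-cycle list is a compact, editable set of canonical mouse
#' cycle genes; it is a configuration default, not an authoritative
#' annotation, and should be replaced when a curated list is available.
#'
#' @param mito_prefixes character, gene-symbol prefixes marking mitochondrial
#'   genes (default `"mt-"`).
#' @param ribo_prefixes character, prefixes marking ribosomal protein genes
#'   (default `c("Rps", "Rpl")`).
#' @param hemoglobin_symbols character, hemoglobin gene symbols.
#' @param cell_cycle_symbols character, cell-cycle gene symbols.
#' @param iexcl_symbols character, sex-linked and immediate-early genes
#'   excluded from highly-variable-gene selection
#'   (default Xist, Fos, Fosb, Jun, Junb, Jund).
#'
#' @return An object of class `"gene_annotations"`.
#' @export
gene_annotations <- function(
    mito_prefixes = "mt-",
    ribo_prefixes = c("Rps", "Rpl"),
    hemoglobin_symbols = c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt"),
    cell_cycle_symbols = c("Mcm2", "Mcm3", "Mcm4", "Mcm5", "Mcm6", "Pcna",
                           "Ccnb1", "Ccne1", "Cdk1", "Top2a", "Mki67",
                           "Birc5", "Aurka", "Bub1", "Cdc20", "Ube2c"),
    iexcl_symbols = c("Xist", "Fos", "Fosb", "Jun", "Junb", "Jund")) {
  structure(
    list(mito_prefixes = mito_prefixes, ribo_prefixes = ribo_prefixes,
         hemoglobin_symbols = hemoglobin_symbols,
         cell_cycle_symbols = cell_cycle_symbols,
         iexcl_symbols = iexcl_symbols),
    class = "gene_annotations")
}

matches_prefix <- function(ids, prefixes) {
  hit <- rep(FALSE, length(ids))
  for (p in prefixes) hit <- hit | startsWith(ids, p)
  hit
}

#' Flag genes by category
#'
#' Sets the per-gene logical flags `mito`, `ribo`, `hemoglobin`,
#' `cell_cycle`, and `iexcl` on a count matrix by prefix / symbol match
#' against a [gene_annotations()] object. Re-application with the same
#' annotations is idempotent; symbols absent from the matrix simply yield
#' empty flag sets.
#'
#' @param x a `count_matrix`.
#' @param ann a `gene_annotations` object.
#' @return `x` with `gene_meta` flag columns filled in.
#' @export
annotate_genes <- function(x, ann = gene_annotations()) {
  stopifnot(inherits(x, "count_matrix"), inherits(ann, "gene_annotations"))
  ids <- x$gene_ids
  x$gene_meta$mito <- matches_prefix(ids, ann$mito_prefixes)
  x$gene_meta$ribo <- matches_prefix(ids, ann$ribo_prefixes)
  x$gene_meta$hemoglobin <- ids %in% ann$hemoglobin_symbols
  x$gene_meta$cell_cycle <- ids %in% ann$cell_cycle_symbols
  x$gene_meta$iexcl <- ids %in% ann$iexcl_symbols
  x
}
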