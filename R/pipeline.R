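#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one list. Defaults
#' are the pipeline's standard operating values: QC thresholds 2,000 UMIs /
#' 1,000 genes / 50 hemoglobin counts / 15% mitochondrial fraction (gene
#' filter 3 counts in 3 cells), 1,500 HVGs in 20 bins, 50 computed PCs with
#' the top 15 retained, a k = 15 cosine kNN graph, Leiden clustering at
#' resolution 1, neuronal refilter at 3,500 UMIs / 2,200 genes, a second
#' neuronal round with 20 retained PCs and k = 10, marker gates
#' `mean_diff > 2` and `AUROC > 0.8`, and sufficiency panel depths
#' 2/3/5/10/15/20. The batch-correction hook defaults to the built-in
#' per-batch centering over the chemistry-by-sex groups; an external
#' integration method can be plugged in through `batch_params$fun` (the
#' recorded default parameters `theta_chemistry = 2`, `theta_sex = 0.5`
#' apply to such an external method).
#'
#' @param thresholds a [qc_thresholds()] object.
#' @param annotations a [gene_annotations()] object.
#' @param n_hvg,n_bins HVG selection parameters.
#' @param n_components,n_keep computed / retained PCs (first round).
#' @param k kNN neighbors (first round).
#' @param neuronal_n_keep,neuronal_k retained PCs and kNN neighbors for the
#'   per-class second round.
#' @param resolution Leiden resolution.
#' @param cluster_backend `"leiden"` or `"greedy"`.
#' @param batch_method `"none"`, `"center"`, or `"external"`.
#' @param batch_vars cell-metadata columns combined into the batch label.
#' @param batch_params parameters recorded for the correction method.
#' @param summary_stat `"median"` or `"mean"` cluster summaries for the
#'   mixture classifiers.
#' @param neuronal_genes,nt_genes signature gene sets.
#' @param min_diff,auroc_pass marker gates.
#' @param sufficiency_ks panel depths for [sufficiency_experiment()];
#'   `NULL` skips the experiment.
#' @param train_fraction stratified split fraction.
#' @param n_trees random-forest size.
#' @param seed global seed; all stage seeds derive from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(thresholds = qc_thresholds(),
                            annotations = gene_annotations(),
                            n_hvg = 1500, n_bins = 20,
                            n_components = 50, n_keep = 15, k = 15,
                            neuronal_n_keep = 20, neuronal_k = 10,
                            resolution = 1, cluster_backend = "leiden",
                            batch_method = "center",
                            batch_vars = c("batch", "sex"),
                            batch_params = list(theta_chemistry = 2,
                                                theta_sex = 0.5),
                            summary_stat = "median",
                            neuronal_genes = c("Snap25", "Syp", "Tubb3",
                                               "Elavl2"),
                            nt_genes = c("Slc17a6", "Slc32a1", "Gad1",
                                         "Hdc"),
                            min_diff = 2, auroc_pass = 0.8,
                            sufficiency_ks = NULL, train_fraction = 0.5,
                            n_trees = 100, seed = 0L) {
  structure(as.list(environment()), class = "pipeline_config")
}

batch_label_from_meta <- function(meta, vars) {
  vars <- intersect(vars, colnames(meta))
  if (!length(vars)) return(NULL)
  do.call(paste, c(meta[vars], sep = "_"))
}

# One HVG -> PCA -> batch-correct -> select -> kNN -> cluster round.
embed_and_cluster <- function(norm, cfg, n_keep, k, seed) {
  hvg <- select_hvgs(norm, n_hvg = min(cfg$n_hvg, ncol(norm$values)),
                     n_bins = cfg$n_bins)
  ncomp <- min(cfg$n_components, length(hvg$selected),
               nrow(norm$values) - 1L)
  emb <- compute_pcs(norm, hvg, n_components = ncomp)
  if (cfg$batch_method != "none") {
    bl <- batch_label_from_meta(norm$cell_meta, cfg$batch_vars)
    if (!is.null(bl) && length(unique(bl)) > 1) {
      emb <- batch_correct(emb, bl, method = cfg$batch_method,
                           params = cfg$batch_params)
    }
  }
  emb <- select_pcs(emb, n_keep = min(n_keep, ncol(emb$coordinates)))
  g <- build_knn(emb, k = k)
  labels <- cluster_graph(g, resolution = cfg$resolution, seed = seed,
                          backend = cfg$cluster_backend)
  list(hvg = hvg, embedding = emb, graph = g, labels = labels)
}

#' Run the full taxonomy pipeline
#'
#' Executes, in order: per-cell QC and the cell filter, the gene filter,
#' depth normalization, HVG selection, PCA, batch correction, PC selection,
#' cosine kNN graph, Leiden clustering, two-state neuronal/non-neuronal
#' mixture classification of the clusters, the stricter neuronal refilter,
#' separate renormalization and reclustering of the neuronal and
#' non-neuronal subsets, three-class neurotransmitter classification of the
#' neuronal clusters, one-vs-rest marker discovery, and (optionally) the
#' marker-sufficiency experiment. All stages derive their seeds from
#' `config$seed`, so a run is reproducible bit-for-bit from its config.
#'
#' @param counts a `count_matrix` (e.g. from [read_counts_triplet()] or
#'   [simulate_counts()]); gene flags are (re)applied from
#'   `config$annotations`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, labels, metrics, marker
#'   and class tables (TSV) and a run manifest (JSON) are written.
#' @return A list of class `"pipeline_result"` with the per-stage objects
#'   (`qc_metrics`, `kept_cells`, `kept_genes`, `norm`, `first_round`,
#'   `neuronal_class`, `neuronal`, `non_neuronal`, `nt_class`, `markers`,
#'   `sufficiency`, `manifest`).
#' @export
run_pipeline <- function(counts, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage_dims <- list()
  note_stage <- function(name, obj_cells, obj_genes) {
    stage_dims[[name]] <<- c(cells = obj_cells, genes = obj_genes)
  }
  counts <- annotate_genes(counts, config$annotations)
  note_stage("input", n_cells(counts), n_genes(counts))

  # cell QC (per-cell criteria; computed per library gives identical sets)
  metrics <- compute_cell_qc(counts)
  kept_cells <- filter_cells(metrics, config$thresholds)
  if (!length(kept_cells)) {
    stopf("qc: no cells pass the quality filters (empty cohort)")
  }
  filtered <- subset_cells(counts, cells = kept_cells)
  kept_genes <- filter_genes(filtered, config$thresholds)
  if (!length(kept_genes)) stopf("qc: no genes pass the gene filter")
  filtered <- subset_cells(filtered, genes = kept_genes)
  note_stage("qc", n_cells(filtered), n_genes(filtered))

  norm <- normalize_counts(filtered)
  note_stage("normalize", nrow(norm$values), ncol(norm$values))

  first <- embed_and_cluster(norm, config, n_keep = config$n_keep,
                             k = config$k, seed = config$seed)
  note_stage("cluster", length(first$labels$labels), NA)

  # neuronal vs non-neuronal on per-cluster signature summaries
  neu_sum <- summarize_cluster_expression(norm, first$labels,
                                          config$neuronal_genes,
                                          stat = config$summary_stat)
  neu_class <- classify_neuronal(neu_sum, seed = config$seed)
  cluster_is_neuronal <- neu_class$class == "neuronal"
  cell_is_neuronal <- cluster_is_neuronal[
    as.character(first$labels$labels)]

  # stricter second-round filter for neuronal cells, then per-class rounds
  neuronal_cells <- which(cell_is_neuronal)
  neuronal_kept <- neuronal_refilter(filtered, neuronal_cells,
                                     config$thresholds)
  non_neuronal_cells <- which(!cell_is_neuronal)
  note_stage("neuronal_refilter", length(neuronal_kept), NA)

  rerun_subset <- function(cells, n_keep, k, seed_offset) {
    if (length(cells) < k + 1) return(NULL)
    sub_counts <- subset_cells(filtered, cells = cells)
    sub_norm <- normalize_counts(sub_counts)
    res <- embed_and_cluster(sub_norm, config, n_keep = n_keep, k = k,
                             seed = config$seed + seed_offset)
    res$cells <- cells
    res$norm <- sub_norm
    res
  }
  neuronal <- rerun_subset(neuronal_kept, config$neuronal_n_keep,
                           config$neuronal_k, 1L)
  non_neuronal <- rerun_subset(non_neuronal_cells, config$n_keep,
                               config$k, 2L)
  if (!is.null(neuronal)) {
    note_stage("neuronal_recluster", length(neuronal$cells),
               neuronal$labels$K)
  }
  if (!is.null(non_neuronal)) {
    note_stage("non_neuronal_recluster", length(non_neuronal$cells),
               non_neuronal$labels$K)
  }

  # neurotransmitter classes over the neuronal clusters
  nt_class <- NULL
  if (!is.null(neuronal) && neuronal$labels$K >= 4) {
    nt_sum <- summarize_cluster_expression(neuronal$norm, neuronal$labels,
                                           config$nt_genes,
                                           stat = config$summary_stat)
    nt_class <- tryCatch(
      classify_neurotransmitter(nt_sum, seed = config$seed),
      error = function(e) {
        warnf("neurotransmitter classification failed: %s",
              conditionMessage(e))
        NULL
      })
  }

  markers <- NULL
  if (!is.null(neuronal) && neuronal$labels$K >= 2) {
    markers <- rank_markers(neuronal$norm, neuronal$labels,
                            min_diff = config$min_diff,
                            auroc_pass = config$auroc_pass)
  }

  sufficiency <- NULL
  if (!is.null(config$sufficiency_ks) && !is.null(neuronal) &&
      neuronal$labels$K >= 2) {
    sufficiency <- sufficiency_experiment(
      neuronal$norm, neuronal$labels, ks = config$sufficiency_ks,
      train_fraction = config$train_fraction, seed = config$seed,
      n_trees = config$n_trees, min_diff = config$min_diff,
      auroc_pass = config$auroc_pass)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("celltaxa")),
    seed = config$seed,
    config = config_snapshot(config),
    stages = stage_dims,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- structure(
    list(qc_metrics = metrics, kept_cells = kept_cells,
         kept_genes = kept_genes, filtered = filtered, norm = norm,
         first_round = first, neuronal_class = neu_class,
         neuronal = neuronal, non_neuronal = non_neuronal,
         nt_class = nt_class, markers = markers,
         sufficiency = sufficiency, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$thresholds <- unclass(snap$thresholds)
  snap$annotations <- unclass(snap$annotations)
  snap$batch_params <- snap$batch_params[
    !vapply(snap$batch_params, is.function, logical(1))]
  snap
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$manifest$stages
  cat("pipeline_result\n")
  for (nm in names(s)) {
    cat(sprintf("  %-22s %s\n", nm,
                paste(names(s[[nm]]), s[[nm]], sep = "=", collapse = " ")))
  }
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(result$qc_metrics, "qc_metrics.tsv")
  lab <- data.frame(cell_id = names(result$first_round$labels$labels),
                    cluster = result$first_round$labels$labels)
  tsv(lab, "clusters_first_round.tsv")
  cls <- data.frame(cluster = names(result$neuronal_class$class),
                    class = unname(result$neuronal_class$class))
  tsv(cls, "cluster_classes.tsv")
  if (!is.null(result$neuronal)) {
    tsv(data.frame(cell_id = names(result$neuronal$labels$labels),
                   cluster = result$neuronal$labels$labels),
        "clusters_neuronal.tsv")
  }
  if (!is.null(result$non_neuronal)) {
    tsv(data.frame(cell_id = names(result$non_neuronal$labels$labels),
                   cluster = result$non_neuronal$labels$labels),
        "clusters_non_neuronal.tsv")
  }
  if (!is.null(result$nt_class)) {
    tsv(data.frame(cluster = names(result$nt_class$class),
                   class = unname(result$nt_class$class)),
        "cluster_nt_classes.tsv")
  }
  if (!is.null(result$markers)) tsv(result$markers, "markers.tsv")
  if (!is.null(result$sufficiency)) {
    tsv(result$sufficiency$results, "sufficiency.tsv")
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
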