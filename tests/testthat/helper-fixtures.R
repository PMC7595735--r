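# Shared fixtures, built in code. The heavier simulated cohort is cached per
# test run so several test files can reuse it.

tiny_counts <- function(counts, cell_prefix = "c", gene_prefix = "g") {
  counts <- as.matrix(counts)
  count_matrix(counts,
               cell_ids = paste0(cell_prefix, seq_len(nrow(counts))),
               gene_ids = paste0(gene_prefix, seq_len(ncol(counts))))
}

# a small annotated matrix with named special genes for QC tests
qc_fixture <- function(counts, gene_ids) {
  cm <- count_matrix(as.matrix(counts),
                     cell_ids = paste0("c", seq_len(nrow(counts))),
                     gene_ids = gene_ids)
  annotate_genes(cm)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a moderate cohort from the preset, shared across test files
preset_sim <- function(scale = 0.05, seed = 7) {
  cached(sprintf("sim_%g_%d", scale, seed), {
    simulate_counts(paper_regime_spec(scale, seed = seed))
  })
}

preset_norm <- function(scale = 0.05, seed = 7) {
  cached(sprintf("norm_%g_%d", scale, seed), {
    sim <- preset_sim(scale, seed)
    kept <- filter_cells(compute_cell_qc(sim$matrix))
    norm <- normalize_counts(subset_cells(sim$matrix, cells = kept))
    list(norm = norm, kept = kept,
         true_cluster = sim$truth$true_cluster[kept],
         true_class = sim$truth$true_class[kept],
         truth = sim$truth)
  })
}

# independent explicit-ROC-integration oracle for the AUROC statistic:
# sweep thresholds over all distinct scores (descending), plot TPR vs FPR,
# integrate by trapezoids. Deliberately does not use ranks.
auroc_by_integration <- function(expr, membership) {
  membership <- as.logical(membership)
  n1 <- sum(membership)
  n2 <- sum(!membership)
  th <- sort(unique(expr), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) sum(expr[membership] >= t) / n1,
                     numeric(1)))
  fpr <- c(0, vapply(th, function(t) sum(expr[!membership] >= t) / n2,
                     numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
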