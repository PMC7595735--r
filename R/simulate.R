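#' Specify a synthetic count-matrix simulation
#'
#' Defines a negative-binomial generative model for droplet scRNA-seq counts
#' with planted cluster structure: each gene in a cell of cluster `c` has mean
#' `baseline_mean * 2^(marker_log2_effect)` if it is one of the cluster's
#' planted markers (plus analogous log2 elevations for neuronal and
#' neurotransmitter signature genes), multiplied by the cell's batch depth
#' factor and its cluster depth factor. Counts are drawn NB with variance
#' `mu + nb_dispersion * mu^2`. A fixed fraction of cells is made to fail
#' quality control by one of three induced modes: `low_depth` (depth scaled
#' by 0.05), `high_mito` (mitochondrial genes forced to at least 20% of the
#' cell's counts), `hemoglobin` (more than 50 hemoglobin counts injected).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_clusters number of planted populations.
#' @param cluster_proportions simplex weights over clusters (recycled uniform
#'   if `NULL`).
#' @param markers_per_cluster planted marker genes per cluster (disjoint
#'   across clusters).
#' @param marker_log2_effect log2 fold elevation of a marker in its home
#'   cluster.
#' @param signature_log2_effect log2 elevation of class signature genes in
#'   the clusters of their class.
#' @param baseline_mean per-gene NB mean scale.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param depth_batch_factors named positive multipliers, one per chemistry
#'   batch; cells are assigned round-robin within cluster over
#'   batch x sex groups.
#' @param sex_labels labels for the two sexes.
#' @param cluster_depth_factors per-cluster positive depth multiplier
#'   (length `n_clusters`, recycled).
#' @param neuronal_cluster_ids integer ids (1-based) of neuronal clusters.
#' @param nt_class_map character vector over clusters: `"GLUT"`, `"GABA"`,
#'   `"HA"` for neuronal clusters, `"NONNEURONAL"` otherwise.
#' @param de_genes_per_cluster number of background genes per cluster that
#'   receive a random cluster-specific expression shift (cell types differ
#'   transcriptome-wide, not only at their markers; this is what separates
#'   the populations in PC space).
#' @param de_log2_sd standard deviation of those random log2 shifts.
#' @param qc_fail_fraction fraction of cells induced to fail QC.
#' @param qc_fail_modes subset of `c("low_depth", "high_mito", "hemoglobin")`.
#' @param batch_gene_shift_log2 optional gene-specific batch effect: log2
#'   shift applied to a tenth of the genes in the last batch (0 disables it);
#'   used to exercise the batch-correction hook.
#' @param seed integer RNG seed; `simulate_counts` is a pure function of the
#'   spec (including this seed).
#'
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_cells = 1000, n_genes = 500, n_clusters = 4,
                            cluster_proportions = NULL,
                            markers_per_cluster = 5, marker_log2_effect = 3,
                            signature_log2_effect = 3,
                            baseline_mean = 1.5, nb_dispersion = 0.5,
                            depth_batch_factors = c(V2 = 0.7, V3 = 1.3),
                            sex_labels = c("M", "F"),
                            cluster_depth_factors = 1,
                            de_genes_per_cluster = 0,
                            de_log2_sd = 1,
                            neuronal_cluster_ids = integer(0),
                            nt_class_map = NULL,
                            qc_fail_fraction = 0,
                            qc_fail_modes = c("low_depth", "high_mito",
                                              "hemoglobin"),
                            batch_gene_shift_log2 = 0,
                            seed = 1L) {
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  cluster_proportions <- cluster_proportions / sum(cluster_proportions)
  if (is.null(nt_class_map)) {
    nt_class_map <- ifelse(seq_len(n_clusters) %in% neuronal_cluster_ids,
                           "GLUT", "NONNEURONAL")
  }
  spec <- structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_clusters = as.integer(n_clusters),
         cluster_proportions = cluster_proportions,
         markers_per_cluster = as.integer(markers_per_cluster),
         marker_log2_effect = marker_log2_effect,
         signature_log2_effect = signature_log2_effect,
         baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
         depth_batch_factors = depth_batch_factors, sex_labels = sex_labels,
         cluster_depth_factors = rep_len(cluster_depth_factors, n_clusters),
         de_genes_per_cluster = as.integer(de_genes_per_cluster),
         de_log2_sd = de_log2_sd,
         neuronal_cluster_ids = as.integer(neuronal_cluster_ids),
         nt_class_map = nt_class_map,
         qc_fail_fraction = qc_fail_fraction,
         qc_fail_modes = match.arg(qc_fail_modes,
                                   c("low_depth", "high_mito", "hemoglobin"),
                                   several.ok = TRUE),
         batch_gene_shift_log2 = batch_gene_shift_log2,
         seed = as.integer(seed)),
    class = "simulation_spec")
  validate_simulation_spec(spec)
  spec
}

validate_simulation_spec <- function(spec) {
  n_special <- length(signature_gene_symbols()) + 13 + 8 + 4 + 16 + 6
  with(spec, {
    if (n_cells < 1 || n_genes < 1 || n_clusters < 1) {
      stopf("dimensions must be positive")
    }
    if (length(cluster_proportions) != n_clusters ||
        abs(sum(cluster_proportions) - 1) > 1e-8) {
      stopf("cluster_proportions must be %d simplex weights", n_clusters)
    }
    if (markers_per_cluster * n_clusters > n_genes - n_special) {
      stopf("not enough genes for %d disjoint markers in %d clusters",
            markers_per_cluster, n_clusters)
    }
    if (qc_fail_fraction < 0 || qc_fail_fraction > 1) {
      stopf("qc_fail_fraction must be in [0, 1]")
    }
    if (any(!neuronal_cluster_ids %in% seq_len(n_clusters))) {
      stopf("neuronal_cluster_ids out of range")
    }
    if (length(nt_class_map) != n_clusters) {
      stopf("nt_class_map must have one entry per cluster")
    }
    bad <- which(seq_len(n_clusters) %in% neuronal_cluster_ids &
                   !nt_class_map %in% c("GLUT", "GABA", "HA"))
    if (length(bad)) stopf("neuronal cluster %d lacks a GLUT/GABA/HA class",
                           bad[1])
    bad <- which(!seq_len(n_clusters) %in% neuronal_cluster_ids &
                   nt_class_map != "NONNEURONAL")
    if (length(bad)) stopf("non-neuronal cluster %d carries an NT class",
                           bad[1])
    invisible(TRUE)
  })
}

signature_gene_symbols <- function() {
  list(neuronal = c("Snap25", "Syp", "Tubb3", "Elavl2"),
       nt = c("Slc17a6", "Slc32a1", "Gad1", "Gad2", "Hdc"))
}

# Gene universe: fixed special symbols first, then a numbered background pool.
simulated_gene_ids <- function(n_genes) {
  sig <- signature_gene_symbols()
  mito <- paste0("mt-", c("Nd1", "Nd2", "Nd3", "Nd4", "Nd4l", "Nd5", "Nd6",
                          "Co1", "Co2", "Co3", "Cytb", "Atp6", "Atp8"))
  ribo <- c(paste0("Rps", c(2, 3, 4, 5)), paste0("Rpl", c(3, 4, 5, 6)))
  ann <- gene_annotations()
  special <- c(sig$neuronal, sig$nt, mito, ribo, ann$hemoglobin_symbols,
               ann$cell_cycle_symbols, ann$iexcl_symbols)
  if (n_genes < length(special) + 1) {
    stopf("n_genes must exceed %d (the fixed signature/QC gene set)",
          length(special))
  }
  c(special, sprintf("Gene%04d", seq_len(n_genes - length(special))))
}

#' Preset emulating the study's data regime
#'
#' A deterministic preset with 20 neuronal-analog clusters (13 glutamatergic,
#' 6 GABAergic, 1 histaminergic) plus 6 non-neuronal clusters, split across
#' 2 chemistry batches x 2 sexes with batch-level depth factors, planted
#' markers, elevated neuronal/neurotransmitter signature genes, deeper
#' neuronal cells, and 6% induced QC-failure cells. `scale` multiplies the
#' cell count (base 24,000) without changing the cluster structure.
#'
#' @param scale positive multiplier on the number of cells.
#' @param seed RNG seed stored in the spec.
#' @return A [simulation_spec()].
#' @export
paper_regime_spec <- function(scale = 1, seed = 1L) {
  stopifnot(scale > 0)
  n_neur <- 20L
  n_non <- 6L
  k <- n_neur + n_non
  props <- c(rep(3.5, n_neur), rep(5, n_non))
  nt <- c(rep("GLUT", 13), rep("GABA", 6), "HA", rep("NONNEURONAL", n_non))
  simulation_spec(
    n_cells = as.integer(round(24000 * scale)), n_genes = 3000L,
    n_clusters = k, cluster_proportions = props / sum(props),
    markers_per_cluster = 5L, marker_log2_effect = 3,
    signature_log2_effect = 3, baseline_mean = 1.5, nb_dispersion = 0.5,
    de_genes_per_cluster = 300L, de_log2_sd = 1.5,
    depth_batch_factors = c(V2 = 0.7, V3 = 1.3),
    cluster_depth_factors = c(rep(2.5, n_neur), rep(1, n_non)),
    neuronal_cluster_ids = seq_len(n_neur), nt_class_map = nt,
    qc_fail_fraction = 0.06, seed = as.integer(seed))
}

#' Simulate a count matrix with planted ground truth
#'
#' Draws counts from the model described in [simulation_spec()] and returns
#' both the (gene-annotated) count matrix and the planted truth. The output
#' is a pure function of the spec, including its seed.
#'
#' @param spec a `simulation_spec`.
#' @return A list with elements `matrix` (a [count_matrix()]) and `truth`, a
#'   list with `true_cluster` (1-based integer per cell), `true_class`
#'   (`"neuronal"`/`"non-neuronal"`), `true_nt` (`"GLUT"`/`"GABA"`/`"HA"`/NA),
#'   `qc_fail` (logical), `qc_fail_mode`, `marker_map` (cluster -> gene ids),
#'   and `signature_genes`.
#' @export
simulate_counts <- function(spec) {
  validate_simulation_spec(spec)
  with_seed(spec$seed, simulate_counts_impl(spec))
}

simulate_counts_impl <- function(spec) {
  n <- spec$n_cells
  ng <- spec$n_genes
  k <- spec$n_clusters
  gene_ids <- simulated_gene_ids(ng)
  sig <- signature_gene_symbols()

  # exact cluster sizes by largest remainder, then a seeded shuffle
  sizes <- floor(spec$cluster_proportions * n)
  rem <- spec$cluster_proportions * n - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    sizes[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      sizes[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  if (any(sizes == 0)) stopf("a cluster received zero cells; increase n_cells")
  true_cluster <- sample(rep.int(seq_len(k), sizes))

  # batch x sex groups, round-robin within cluster so groups span clusters
  batches <- names(spec$depth_batch_factors)
  groups <- expand.grid(sex = spec$sex_labels, batch = batches,
                        stringsAsFactors = FALSE)
  gidx <- integer(n)
  for (c in seq_len(k)) {
    cells <- which(true_cluster == c)
    gidx[cells] <- ((seq_along(cells) - 1) %% nrow(groups)) + 1
  }
  sex <- groups$sex[gidx]
  batch <- groups$batch[gidx]

  # planted markers: disjoint blocks of the background pool
  background <- setdiff(gene_ids, c(sig$neuronal, sig$nt))
  background <- background[!matches_prefix(background, c("mt-", "Rps", "Rpl"))]
  ann <- gene_annotations()
  background <- setdiff(background, c(ann$hemoglobin_symbols,
                                      ann$cell_cycle_symbols,
                                      ann$iexcl_symbols))
  marker_map <- lapply(seq_len(k), function(c) {
    background[((c - 1) * spec$markers_per_cluster + 1):
                 (c * spec$markers_per_cluster)]
  })
  names(marker_map) <- as.character(seq_len(k))

  # per-cluster mean vectors (log2 effects on top of the baseline)
  nt_gene <- c(GLUT = "Slc17a6", GABA = "Slc32a1", HA = "Hdc")
  cluster_mu <- matrix(spec$baseline_mean, nrow = k, ncol = ng,
                       dimnames = list(NULL, gene_ids))
  # hemoglobin in brain tissue is ambient contamination, not expression:
  # keep its baseline low so only the injected failure mode crosses QC
  cluster_mu[, ann$hemoglobin_symbols] <-
    cluster_mu[, ann$hemoglobin_symbols] * 0.1
  for (c in seq_len(k)) {
    if (spec$markers_per_cluster > 0) {
      cluster_mu[c, marker_map[[c]]] <-
        cluster_mu[c, marker_map[[c]]] * 2^spec$marker_log2_effect
    }
    if (c %in% spec$neuronal_cluster_ids) {
      cluster_mu[c, sig$neuronal] <-
        cluster_mu[c, sig$neuronal] * 2^spec$signature_log2_effect
      cls <- spec$nt_class_map[c]
      cluster_mu[c, nt_gene[cls]] <-
        cluster_mu[c, nt_gene[cls]] * 2^spec$signature_log2_effect
      if (cls == "GABA") {  # GABAergic cells co-express both Gad paralogs
        cluster_mu[c, c("Gad1", "Gad2")] <-
          cluster_mu[c, c("Gad1", "Gad2")] * 2^spec$signature_log2_effect
      }
    }
    if (spec$de_genes_per_cluster > 0) {
      # transcriptome-wide cluster identity: random log2 shifts on a subset
      # of background genes (markers and signature genes stay as planted)
      pool <- setdiff(background, unlist(marker_map))
      de <- sample(pool, min(spec$de_genes_per_cluster, length(pool)))
      cluster_mu[c, de] <- cluster_mu[c, de] *
        2^rnorm(length(de), 0, spec$de_log2_sd)
    }
    cluster_mu[c, ] <- cluster_mu[c, ] * spec$cluster_depth_factors[c]
  }

  # induced QC failures: round(n * fraction) cells, modes cycled
  n_fail <- as.integer(round(spec$qc_fail_fraction * n))
  fail_cells <- if (n_fail > 0) sort(sample.int(n, n_fail)) else integer(0)
  qc_fail <- seq_len(n) %in% fail_cells
  qc_fail_mode <- rep(NA_character_, n)
  if (n_fail > 0) {
    qc_fail_mode[fail_cells] <-
      rep_len(spec$qc_fail_modes, n_fail)
  }

  # optional gene-specific batch shift in the last batch
  shift_genes <- integer(0)
  if (spec$batch_gene_shift_log2 != 0) {
    shift_genes <- sample.int(ng, max(1L, ng %/% 10L))
  }

  depth <- unname(spec$depth_batch_factors[batch])
  depth[qc_fail_mode %in% "low_depth"] <-
    depth[qc_fail_mode %in% "low_depth"] * 0.05
  size <- 1 / spec$nb_dispersion

  counts <- matrix(0L, nrow = n, ncol = ng)
  for (c in seq_len(k)) {
    for (b in batches) {
      cells <- which(true_cluster == c & batch == b)
      if (!length(cells)) next
      mu <- outer(depth[cells], cluster_mu[c, ])
      if (length(shift_genes) && b == batches[length(batches)]) {
        mu[, shift_genes] <- mu[, shift_genes] * 2^spec$batch_gene_shift_log2
      }
      counts[cells, ] <- rnbinom(length(mu), size = size, mu = mu)
    }
  }

  # deterministic QC-failure injections on the drawn counts
  mito_idx <- which(matches_prefix(gene_ids, "mt-"))
  hgb_idx <- which(gene_ids %in% ann$hemoglobin_symbols)
  for (i in which(qc_fail_mode %in% "high_mito")) {
    tot <- sum(counts[i, ])
    m <- sum(counts[i, mito_idx])
    need <- ceiling((0.2 * tot - m) / 0.8) + 1
    if (need > 0) counts[i, mito_idx[1]] <- counts[i, mito_idx[1]] + need
  }
  for (i in which(qc_fail_mode %in% "hemoglobin")) {
    counts[i, hgb_idx] <- counts[i, hgb_idx] +
      as.integer(20 + rpois(length(hgb_idx), 5))
  }

  cell_ids <- sprintf("cell%05d", seq_len(n))
  cm <- count_matrix(counts, cell_ids, gene_ids,
                     cell_meta = data.frame(
                       sample = paste(sex, batch, sep = "_"),
                       sex = sex, batch = batch,
                       stringsAsFactors = FALSE))
  cm <- annotate_genes(cm, ann)

  true_class <- ifelse(true_cluster %in% spec$neuronal_cluster_ids,
                       "neuronal", "non-neuronal")
  true_nt <- ifelse(true_class == "neuronal",
                    spec$nt_class_map[true_cluster], NA_character_)
  list(matrix = cm,
       truth = list(true_cluster = true_cluster, true_class = true_class,
                    true_nt = true_nt, qc_fail = qc_fail,
                    qc_fail_mode = qc_fail_mode, marker_map = marker_map,
                    signature_genes = sig))
}

#' Write a simulation to disk
#'
#' Writes the count matrix as a 10x-style triplet plus two truth tables:
#' `truth_cells.tsv` (cell_id, true_cluster, true_class, true_nt, qc_fail)
#' and `truth_markers.tsv` (cluster, marker_gene).
#'
#' @param sim result of [simulate_counts()].
#' @param out_dir output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_simulation <- function(sim, out_dir) {
  write_counts_triplet(sim$matrix, out_dir)
  cells <- data.frame(cell_id = sim$matrix$cell_ids,
                      true_cluster = sim$truth$true_cluster,
                      true_class = sim$truth$true_class,
                      true_nt = sim$truth$true_nt,
                      qc_fail = sim$truth$qc_fail)
  write.table(cells, file.path(out_dir, "truth_cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  markers <- data.frame(
    cluster = rep(names(sim$truth$marker_map),
                  lengths(sim$truth$marker_map)),
    marker_gene = unlist(sim$truth$marker_map, use.names = FALSE))
  write.table(markers, file.path(out_dir, "truth_markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
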