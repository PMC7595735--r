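subset_norm <- function(norm, cells) {
  structure(
    list(values = norm$values[cells, , drop = FALSE],
         size_factors = norm$size_factors[cells],
         scale_target = norm$scale_target,
         cell_ids = norm$cell_ids[cells], gene_ids = norm$gene_ids,
         cell_meta = norm$cell_meta[cells, , drop = FALSE],
         gene_meta = norm$gene_meta),
    class = "normalized_matrix")
}

#' Principal components of the HVG-restricted expression matrix
#'
#' PCA on the normalized matrix restricted to the selected highly variable
#' genes, per-gene mean-centered (no unit-variance scaling by default). The
#' sign of each component is fixed by making its largest-magnitude gene
#' loading positive, so results are deterministic.
#'
#' @param norm a `normalized_matrix`.
#' @param hvg an `hvg_selection` (or a character vector of gene ids).
#' @param n_components number of components (reduced with a warning when
#'   there are fewer cells).
#' @param scale_genes also scale genes to unit variance before PCA.
#' @return An object of class `"embedding"`: `coordinates` (cells x
#'   components), `variance_ratio` (per-component fraction of total
#'   variance, non-increasing), `loadings`, `batch_corrected`,
#'   `correction_params`.
#' @export
compute_pcs <- function(norm, hvg, n_components = 50, scale_genes = FALSE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  genes <- if (inherits(hvg, "hvg_selection")) hvg$selected else hvg
  if (length(genes) < n_components) {
    stopf("need at least n_components = %d selected genes, have %d",
          n_components, length(genes))
  }
  v <- norm$values[, genes, drop = FALSE]
  max_rank <- min(nrow(v) - 1L, ncol(v))
  if (n_components > max_rank) {
    warnf("reducing n_components from %d to %d (matrix rank limit)",
          n_components, max_rank)
    n_components <- max_rank
  }
  p <- prcomp(v, center = TRUE, scale. = scale_genes, rank. = n_components)
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  vr <- p$sdev[seq_len(n_components)]^2 / sum(p$sdev^2)
  coords <- p$x[, seq_len(n_components), drop = FALSE]
  rownames(coords) <- norm$cell_ids
  structure(
    list(coordinates = coords, variance_ratio = vr,
         loadings = p$rotation[, seq_len(n_components), drop = FALSE],
         batch_corrected = FALSE, correction_params = NULL,
         cell_ids = norm$cell_ids, cell_meta = norm$cell_meta),
    class = "embedding")
}

#' Batch-correct an embedding
#'
#' Pluggable correction of the PC coordinates for batch structure. Method
#' `"none"` is the identity; `"center"` is the built-in reference: per-batch
#' mean subtraction of each component (after which batch centroids
#' coincide); `"external"` delegates to a user-supplied integration function
#' `params$fun(coordinates, batch_labels, params)` — the hook under which a
#' published integration algorithm (e.g. Harmony with theta_chemistry = 2,
#' theta_sex = 0.5) can be plugged in, with `params` recorded verbatim.
#'
#' @param emb an `embedding`.
#' @param batch_labels one label per cell (a factor or character vector; use
#'   an interaction label to correct several variables jointly).
#' @param method `"none"`, `"center"`, or `"external"`.
#' @param params list of method parameters, recorded in the result.
#' @return The corrected `embedding`, flagged `batch_corrected`.
#' @export
batch_correct <- function(emb, batch_labels = NULL,
                          method = c("none", "center", "external"),
                          params = list()) {
  stopifnot(inherits(emb, "embedding"))
  method <- match.arg(method)
  coords <- emb$coordinates
  if (method != "none") {
    if (is.null(batch_labels)) stopf("batch_labels required for method '%s'",
                                     method)
    if (length(batch_labels) != nrow(coords)) {
      stopf("need one batch label per cell")
    }
  }
  if (method == "center") {
    batch_labels <- as.character(batch_labels)
    for (b in unique(batch_labels)) {
      idx <- which(batch_labels == b)
      if (length(idx) == 1) {
        warnf("batch '%s' has a single cell; passed through uncorrected", b)
        next
      }
      coords[idx, ] <- sweep(coords[idx, , drop = FALSE], 2,
                             colMeans(coords[idx, , drop = FALSE]))
    }
  } else if (method == "external") {
    if (!is.function(params$fun)) {
      stopf("method 'external' requires a function in params$fun")
    }
    coords <- params$fun(coords, batch_labels, params)
    stopifnot(identical(dim(coords), dim(emb$coordinates)))
  }
  emb$coordinates <- coords
  emb$batch_corrected <- method != "none"
  emb$correction_params <- c(list(method = method),
                             params[setdiff(names(params), "fun")])
  emb
}

#' Keep the components with the highest variance ratios
#'
#' Retains the `n_keep` components with largest `variance_ratio`, ties
#' resolved by original component order; the retained components keep their
#' original relative order.
#'
#' @param emb an `embedding`.
#' @param n_keep number of components to retain.
#' @return The reduced `embedding`.
#' @export
select_pcs <- function(emb, n_keep = 15) {
  stopifnot(inherits(emb, "embedding"),
            n_keep <= length(emb$variance_ratio))
  ord <- order(-emb$variance_ratio, seq_along(emb$variance_ratio))
  keep <- sort(ord[seq_len(n_keep)])
  emb$coordinates <- emb$coordinates[, keep, drop = FALSE]
  emb$variance_ratio <- emb$variance_ratio[keep]
  emb$loadings <- emb$loadings[, keep, drop = FALSE]
  emb
}

cosine_distance_matrix <- function(coords) {
  nrm <- sqrt(rowSums(coords^2))
  nrm[nrm == 0] <- 1  # zero vectors get similarity 0 to everything
  u <- coords / nrm
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0  # numerical noise
  d
}

#' Exact k-nearest-neighbor graph under cosine distance
#'
#' Brute-force exact kNN per cell in the embedding, cosine metric
#' (distances in \[0, 2\]); ties broken by cell index; no self-edges.
#'
#' @param emb an `embedding` (or a plain coordinate matrix).
#' @param k neighbors per cell.
#' @return An object of class `"neighbor_graph"`: `k`, `nn_index` (cells x
#'   k), `nn_dist`, `metric`, `cell_ids`.
#' @export
build_knn <- function(emb, k = 15) {
  coords <- if (inherits(emb, "embedding")) emb$coordinates else emb
  n <- nrow(coords)
  if (n < k + 1) stopf("need at least k + 1 = %d cells, have %d", k + 1, n)
  d <- cosine_distance_matrix(coords)
  diag(d) <- Inf
  nn_index <- matrix(0L, n, k)
  nn_dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))[seq_len(k)]
    nn_index[i, ] <- ord
    nn_dist[i, ] <- d[i, ord]
  }
  ids <- if (inherits(emb, "embedding")) emb$cell_ids else rownames(coords)
  structure(list(k = k, nn_index = nn_index, nn_dist = nn_dist,
                 metric = "cosine", cell_ids = ids),
            class = "neighbor_graph")
}

knn_to_igraph <- function(g) {
  n <- nrow(g$nn_index)
  edges <- cbind(rep(seq_len(n), g$k), as.vector(g$nn_index))
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(ig)
}

#' Graph community detection
#'
#' Partitions the symmetrized kNN graph into communities. Backend
#' `"leiden"` (default) runs the Leiden algorithm with a modularity
#' objective at the given resolution; backend `"greedy"` is a deterministic
#' agglomerative modularity reference (no resolution parameter). Identical
#' inputs and seed give identical labels.
#'
#' @param g a `neighbor_graph` (or an igraph object).
#' @param resolution resolution parameter for the Leiden backend.
#' @param seed RNG seed for the Leiden backend.
#' @param backend `"leiden"` or `"greedy"`.
#' @return An object of class `"cluster_labels"`: `labels` (0-based
#'   contiguous integers, named by cell id when available), `K`, and the
#'   method, resolution and seed used.
#' @export
cluster_graph <- function(g, resolution = 1, seed = 0L,
                          backend = c("leiden", "greedy")) {
  backend <- match.arg(backend)
  ig <- if (inherits(g, "neighbor_graph")) knn_to_igraph(g) else g
  ids <- if (inherits(g, "neighbor_graph")) g$cell_ids else NULL
  memb <- switch(backend,
    leiden = with_seed(seed, igraph::membership(
      igraph::cluster_leiden(ig, objective_function = "modularity",
                             resolution = resolution, n_iterations = 10))),
    greedy = igraph::membership(igraph::cluster_fast_greedy(ig)))
  labels <- relabel_contiguous(as.integer(memb))
  if (!is.null(ids)) names(labels) <- ids
  structure(list(labels = labels, K = length(unique(labels)),
                 method = backend, resolution = resolution, seed = seed,
                 parent = NULL),
            class = "cluster_labels")
}

# 0-based contiguous labels in order of first occurrence
relabel_contiguous <- function(x) {
  match(x, unique(x)) - 1L
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("cluster_labels: %d cells in %d clusters (%s)\n",
              length(x$labels), x$K, x$method))
  if (!is.null(x$parent)) {
    cat("  subclustered from parent cluster(s):",
        paste(x$parent, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Iteratively subcluster selected clusters
#'
#' Reruns the embedding/clustering chain (HVG selection, PCA, batch
#' correction, PC selection, kNN graph, community detection) on the cells of
#' the selected clusters only, returning child labels that carry the parent
#' lineage.
#'
#' @param norm the `normalized_matrix` of the full cohort.
#' @param labels a `cluster_labels` object over the same cells.
#' @param target_clusters cluster ids (values of `labels$labels`) to
#'   subcluster jointly.
#' @param params list overriding defaults: `n_hvg`, `n_bins`,
#'   `n_components`, `n_keep`, `k`, `resolution`, `seed`, `backend`,
#'   `batch_method`, `batch_labels`.
#' @return A `cluster_labels` object over the subset cells, with `parent`
#'   recording `target_clusters` and `parent_cells` the subset indices.
#' @export
subcluster <- function(norm, labels, target_clusters, params = list()) {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(labels, "cluster_labels"))
  if (!length(target_clusters)) stopf("target_clusters is empty")
  if (!all(target_clusters %in% labels$labels)) {
    stopf("target cluster(s) %s not present",
          paste(setdiff(target_clusters, labels$labels), collapse = ", "))
  }
  p <- modifyList(list(n_hvg = 1500, n_bins = 20, n_components = 50,
                       n_keep = 15, k = 15, resolution = 1, seed = 0L,
                       backend = "leiden", batch_method = "none",
                       batch_labels = NULL),
                  params)
  cells <- which(labels$labels %in% target_clusters)
  if (length(cells) < p$k + 1) {
    stopf("subset of %d cells is too small for k = %d", length(cells), p$k)
  }
  sub <- subset_norm(norm, cells)
  hvg <- select_hvgs(sub, n_hvg = min(p$n_hvg, ncol(sub$values)),
                     n_bins = p$n_bins)
  ncomp <- min(p$n_components, length(hvg$selected), length(cells) - 1L)
  emb <- compute_pcs(sub, hvg, n_components = ncomp)
  if (p$batch_method != "none") {
    bl <- if (!is.null(p$batch_labels)) p$batch_labels[cells]
          else sub$cell_meta$batch
    emb <- batch_correct(emb, bl, method = p$batch_method)
  }
  emb <- select_pcs(emb, n_keep = min(p$n_keep, ncol(emb$coordinates)))
  g <- build_knn(emb, k = p$k)
  child <- cluster_graph(g, resolution = p$resolution, seed = p$seed,
                         backend = p$backend)
  child$parent <- target_clusters
  child$parent_cells <- cells
  child
}
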