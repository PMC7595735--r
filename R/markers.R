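#' Mean-difference candidate genes for one cluster
#'
#' One-vs-rest candidate gate: genes whose mean normalized expression inside
#' cluster `c` exceeds the mean over all other cells by strictly more than
#' `min_diff` (log2 units).
#'
#' @param norm a `normalized_matrix`.
#' @param labels a `cluster_labels` (or integer vector per cell).
#' @param cluster the cluster id.
#' @param min_diff strict lower bound on `mean_in - mean_out`.
#' @return Character vector of candidate gene ids.
#' @export
mean_diff_candidates <- function(norm, labels, cluster, min_diff = 2) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  inside <- lab == cluster
  if (!any(inside)) stopf("cluster %s is empty", cluster)
  if (all(inside)) stopf("cluster %s contains every cell; no out-group",
                         cluster)
  mean_in <- colMeans(norm$values[inside, , drop = FALSE])
  mean_out <- colMeans(norm$values[!inside, , drop = FALSE])
  norm$gene_ids[mean_in - mean_out > min_diff]
}

#' One-vs-rest AUROC of an expression vector
#'
#' The area under the ROC curve obtained by sweeping a rank threshold over
#' cells ordered by expression: at each threshold, cells at or above it are
#' called members of the cluster. Computed through the rank-sum identity
#' `AUROC = (R1 - n1 (n1 + 1) / 2) / (n1 n2)` with mid-rank tie handling,
#' which equals explicit trapezoidal integration of that ROC curve.
#'
#' @param expr numeric expression values, one per cell.
#' @param membership logical (or 0/1) indicator of cluster membership.
#' @return AUROC in \[0, 1\] (0.5 means uninformative).
#' @export
auroc_score <- function(expr, membership) {
  membership <- as.logical(membership)
  n1 <- sum(membership)
  n2 <- sum(!membership)
  if (n1 == 0 || n2 == 0) stopf("both classes must be nonempty")
  r <- rank(expr, ties.method = "average")
  (sum(r[membership]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' One-vs-rest marker table over all clusters
#'
#' For every cluster, applies the mean-difference gate
#' (`mean_in - mean_out > min_diff`) and computes the one-vs-rest AUROC of
#' each candidate gene; genes with `auroc > auroc_pass` are flagged as
#' passing markers. Within each cluster, rows are sorted by AUROC
#' descending, ties by mean difference then gene id.
#'
#' @param norm a `normalized_matrix`.
#' @param labels a `cluster_labels` (or integer vector); at least 2 clusters.
#' @param min_diff candidate gate on the log2 mean difference.
#' @param auroc_pass strict AUROC pass threshold.
#' @return An object of class `"marker_table"`: a data.frame with columns
#'   `cluster`, `gene`, `mean_in`, `mean_out`, `mean_diff`, `auroc`, `pass`,
#'   `n_cluster`.
#' @export
rank_markers <- function(norm, labels, min_diff = 2, auroc_pass = 0.8) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  cl <- sort(unique(lab))
  if (length(cl) < 2) stopf("need at least 2 clusters")
  v <- norm$values
  sums <- rowsum(v, lab)
  sizes <- as.vector(table(factor(lab, levels = cl)))
  total <- colSums(v)
  rows <- list()
  for (i in seq_along(cl)) {
    mean_in <- sums[i, ] / sizes[i]
    mean_out <- (total - sums[i, ]) / (nrow(v) - sizes[i])
    diff <- mean_in - mean_out
    cand <- which(diff > min_diff)
    if (!length(cand)) next
    inside <- lab == cl[i]
    auc <- vapply(cand, function(g) auroc_score(v[, g], inside), numeric(1))
    df <- data.frame(cluster = cl[i], gene = norm$gene_ids[cand],
                     mean_in = unname(mean_in[cand]),
                     mean_out = unname(mean_out[cand]),
                     mean_diff = unname(diff[cand]), auroc = auc,
                     pass = auc > auroc_pass, n_cluster = sizes[i],
                     row.names = NULL)
    df <- df[order(-df$auroc, -df$mean_diff, df$gene), ]
    rows[[length(rows) + 1]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), gene = character(0),
               mean_in = numeric(0), mean_out = numeric(0),
               mean_diff = numeric(0), auroc = numeric(0),
               pass = logical(0), n_cluster = integer(0))
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Wilcoxon rank-sum cross-check for one cluster
#'
#' Ranks all genes by the standardized one-vs-rest rank-sum statistic
#' (tie-corrected normal approximation, in-group high expression positive),
#' the cross-check against the AUROC marker ranking.
#'
#' @param norm a `normalized_matrix`.
#' @param labels a `cluster_labels` (or integer vector).
#' @param cluster the cluster to test.
#' @param top_n rows to return (default all genes).
#' @return data.frame with `gene`, `U`, `z`, `p` (two-sided), sorted by `z`
#'   descending.
#' @export
wilcoxon_cross_check <- function(norm, labels, cluster, top_n = Inf) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  inside <- lab == cluster
  n1 <- sum(inside)
  n2 <- sum(!inside)
  if (n1 < 2 || n2 < 2) stopf("both groups need at least 2 cells")
  n <- n1 + n2
  v <- norm$values
  res <- apply(v, 2, function(x) {
    r <- rank(x, ties.method = "average")
    u <- sum(r[inside]) - n1 * (n1 + 1) / 2
    tie <- table(x)
    tie_term <- sum(tie^3 - tie) / (n * (n - 1))
    sd_u <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- if (sd_u == 0) 0 else (u - n1 * n2 / 2) / sd_u
    c(u, z)
  })
  df <- data.frame(gene = norm$gene_ids, U = res[1, ], z = res[2, ],
                   p = 2 * stats::pnorm(-abs(res[2, ])), row.names = NULL)
  df <- df[order(-df$z, df$gene), ]
  head(df, top_n)
}

#' Stratified train/test split of clustered cells
#'
#' Partitions cells into disjoint, exhaustive train and test sets with a
#' proportional number of cells from each cluster: per cluster the train
#' count is `train_fraction * size` rounded half-up, clamped so both sides
#' get at least one cell. The within-cluster shuffle is seeded.
#'
#' @param labels a `cluster_labels` (or integer vector); every cluster must
#'   have at least 2 cells.
#' @param train_fraction fraction of each cluster assigned to training.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.5, seed = 0L) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  stopifnot(train_fraction > 0, train_fraction < 1)
  train <- integer(0)
  with_seed(seed, {
    for (c in sort(unique(lab))) {
      cells <- which(lab == c)
      if (length(cells) < 2) {
        stopf("cluster %s has a single cell and cannot be split", c)
      }
      n_train <- round_half_up(train_fraction * length(cells))
      n_train <- min(max(n_train, 1), length(cells) - 1)
      train <- c(train, sample(cells)[seq_len(n_train)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(lab), train))
}

#' Marker panel from the top-k genes of each cluster
#'
#' Union over clusters of the top `k` genes by AUROC (after the
#' mean-difference gate). Clusters with fewer than `k` candidates contribute
#' all they have and are recorded in the `shortfall` attribute.
#'
#' @param norm a `normalized_matrix` (typically the training split).
#' @param labels matching `cluster_labels` (or integer vector).
#' @param k genes per cluster.
#' @param min_diff,auroc_pass marker gates passed to [rank_markers()].
#' @return Character vector of unique panel genes with attribute
#'   `shortfall` (named logical per cluster).
#' @export
top_k_panel <- function(norm, labels, k, min_diff = 2, auroc_pass = 0.8) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  if (k == 0) {
    out <- character(0)
    attr(out, "shortfall") <- setNames(rep(FALSE, length(unique(lab))),
                                       sort(unique(lab)))
    return(out)
  }
  tab <- rank_markers(norm, lab, min_diff = min_diff,
                      auroc_pass = auroc_pass)
  cl <- sort(unique(lab))
  shortfall <- setNames(rep(FALSE, length(cl)), as.character(cl))
  genes <- character(0)
  for (c in cl) {
    top <- head(tab$gene[tab$cluster == c], k)
    if (length(top) < k) shortfall[as.character(c)] <- TRUE
    genes <- c(genes, top)
  }
  out <- unique(genes)
  attr(out, "shortfall") <- shortfall
  out
}

#' Marker-panel sufficiency experiment
#'
#' Tests whether a small marker panel suffices to identify the clusters:
#' cells are split (stratified) into train and test halves, the marker table
#' is recomputed on the training half only, and for each `k` a random-forest
#' classifier is trained on the top-k-per-cluster panel genes and evaluated
#' on the held-out half.
#'
#' @param norm a `normalized_matrix`.
#' @param labels matching `cluster_labels` (or integer vector).
#' @param ks panel depths to evaluate.
#' @param train_fraction stratified train fraction.
#' @param seed seed for the split and the forests.
#' @param n_trees trees per forest.
#' @param min_diff,auroc_pass marker gates.
#' @return An object of class `"sufficiency_result"`: `results` (one row per
#'   k: `k`, `panel_size`, `accuracy`), `panels`, `per_cluster_accuracy`,
#'   `confusion` (per-k K x K matrices, rows = true cluster), and split /
#'   classifier metadata.
#' @export
sufficiency_experiment <- function(norm, labels,
                                   ks = c(2, 3, 5, 10, 15, 20),
                                   train_fraction = 0.5, seed = 0L,
                                   n_trees = 100, min_diff = 2,
                                   auroc_pass = 0.8) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  split <- stratified_split(lab, train_fraction, seed)
  train_norm <- subset_norm(norm, split$train)
  train_lab <- lab[split$train]
  test_lab <- lab[split$test]
  levels <- as.character(sort(unique(lab)))

  results <- data.frame(k = ks, panel_size = NA_integer_,
                        accuracy = NA_real_)
  panels <- list()
  confusion <- list()
  per_cluster <- list()
  for (i in seq_along(ks)) {
    panel <- top_k_panel(train_norm, train_lab, ks[i], min_diff = min_diff,
                         auroc_pass = auroc_pass)
    if (!length(panel)) stopf("empty marker panel for k = %d", ks[i])
    xtr <- train_norm$values[, panel, drop = FALSE]
    xte <- norm$values[split$test, panel, drop = FALSE]
    ytr <- factor(as.character(train_lab), levels = levels)
    fit <- with_seed(seed, randomForest::randomForest(
      x = xtr, y = ytr, ntree = n_trees))
    pred <- predict(fit, xte)
    yte <- factor(as.character(test_lab), levels = levels)
    conf <- table(true = yte, predicted = pred)
    acc <- sum(diag(conf)) / length(yte)
    results$panel_size[i] <- length(panel)
    results$accuracy[i] <- acc
    panels[[as.character(ks[i])]] <- panel
    confusion[[as.character(ks[i])]] <- conf
    per_cluster[[as.character(ks[i])]] <-
      diag(conf) / pmax(rowSums(conf), 1)
  }
  structure(
    list(results = results, panels = panels, confusion = confusion,
         per_cluster_accuracy = per_cluster,
         split = list(train_fraction = train_fraction, seed = seed,
                      n_train = length(split$train),
                      n_test = length(split$test)),
         classifier = list(type = "randomForest", n_trees = n_trees,
                           seed = seed)),
    class = "sufficiency_result")
}

#' @export
print.sufficiency_result <- function(x, ...) {
  cat("sufficiency_result (random forest,", x$classifier$n_trees,
      "trees):\n")
  print(transform(x$results, accuracy = round(accuracy, 4)),
        row.names = FALSE)
  invisible(x)
}
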