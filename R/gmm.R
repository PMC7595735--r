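#' Summarize expression of signature genes per cluster
#'
#' Entry (c, g) is the summary statistic (median by default) of normalized
#' expression of gene g over the cells of cluster c.
#'
#' @param norm a `normalized_matrix`.
#' @param labels a `cluster_labels` object (or an integer vector per cell).
#' @param genes character vector of gene ids present in the matrix.
#' @param stat `"median"` or `"mean"`.
#' @return A clusters x genes numeric matrix, rows named by cluster id.
#' @export
summarize_cluster_expression <- function(norm, labels, genes,
                                         stat = c("median", "mean")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  stat <- match.arg(stat)
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  if (length(lab) != nrow(norm$values)) stopf("one label per cell required")
  missing <- setdiff(genes, norm$gene_ids)
  if (length(missing)) {
    stopf("gene(s) not in matrix: %s", paste(missing, collapse = ", "))
  }
  cl <- sort(unique(lab))
  fn <- if (stat == "median") median else mean
  out <- matrix(0, length(cl), length(genes),
                dimnames = list(as.character(cl), genes))
  for (i in seq_along(cl)) {
    cells <- which(lab == cl[i])
    if (!length(cells)) stopf("cluster %s is empty", cl[i])
    out[i, ] <- apply(norm$values[cells, genes, drop = FALSE], 2, fn)
  }
  out
}

# Diagonal-covariance Gaussian mixture fit by EM with seeded
# nearest-mean initializations and a variance floor.
fit_diag_gmm <- function(X, k, seed = 0L, n_restarts = 10, max_iter = 500,
                         tol = 1e-8, var_floor = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < k) stopf("cannot fit %d components to %d observations", k, n)
  if (all(apply(X, 2, var) < 1e-12)) {
    stopf("degenerate fit: all observations are identical")
  }

  log_comp_dens <- function(means, vars, weights) {
    out <- matrix(0, n, k)
    for (j in seq_len(k)) {
      out[, j] <- log(weights[j]) +
        rowSums(dnorm(X, mean = matrix(means[j, ], n, d, byrow = TRUE),
                      sd = matrix(sqrt(vars[j, ]), n, d, byrow = TRUE),
                      log = TRUE))
    }
    out
  }

  run_em <- function(assign0) {
    means <- matrix(0, k, d)
    vars <- matrix(0, k, d)
    weights <- numeric(k)
    for (j in seq_len(k)) {
      idx <- which(assign0 == j)
      means[j, ] <- colMeans(X[idx, , drop = FALSE])
      vars[j, ] <- pmax(apply(X[idx, , drop = FALSE], 2, var), var_floor)
      vars[j, is.na(vars[j, ])] <- var_floor
      weights[j] <- length(idx) / n
    }
    ll_old <- -Inf
    resp <- NULL
    for (it in seq_len(max_iter)) {
      lg <- log_comp_dens(means, vars, weights)
      m <- apply(lg, 1, max)
      lse <- m + log(rowSums(exp(lg - m)))
      ll <- sum(lse)
      resp <- exp(lg - lse)
      nk <- colSums(resp)
      nk <- pmax(nk, 1e-12)
      weights <- nk / n
      for (j in seq_len(k)) {
        means[j, ] <- colSums(resp[, j] * X) / nk[j]
        dev <- sweep(X, 2, means[j, ])^2
        vars[j, ] <- pmax(colSums(resp[, j] * dev) / nk[j], var_floor)
      }
      done <- ll - ll_old < tol && it > 1
      ll_old <- ll
      if (done) break
    }
    list(means = means, vars = vars, weights = weights, resp = resp,
         loglik = ll_old, iterations = it)
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- X[sample.int(n, k), , drop = FALSE]
      dmat <- vapply(seq_len(k), function(j) {
        rowSums(sweep(X, 2, centers[j, ])^2)
      }, numeric(n))
      assign0 <- max.col(-dmat, ties.method = "first")
      if (length(unique(assign0)) < k) {
        assign0[sample.int(n, k)] <- seq_len(k)  # revive empty components
      }
      fit <- tryCatch(run_em(assign0), error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (is.null(best)) stopf("degenerate fit: EM failed in all restarts")
    best
  })
}

new_gmm_classification <- function(fit, comp_names, summary, seed) {
  comp <- max.col(fit$resp, ties.method = "first")
  cls <- comp_names[comp]
  names(cls) <- rownames(summary)
  structure(
    list(class = cls, component = comp, component_names = comp_names,
         means = fit$means, vars = fit$vars, weights = fit$weights,
         responsibilities = fit$resp, loglik = fit$loglik,
         iterations = fit$iterations, seed = seed,
         genes = colnames(summary)),
    class = "gmm_classification")
}

#' @export
print.gmm_classification <- function(x, ...) {
  cat(sprintf("gmm_classification: %d observations, components: %s\n",
              nrow(x$responsibilities),
              paste(x$component_names, collapse = "/")))
  print(table(x$class))
  invisible(x)
}

#' Two-state neuronal vs non-neuronal classification
#'
#' Fits a two-component Gaussian mixture (diagonal covariance, EM) to the
#' per-cluster summaries of the four pan-neuronal signature genes
#' (Snap25/Syp/Tubb3/Elavl2 by default). The component with the larger mean
#' vector norm is called `"neuronal"`; each cluster is labeled by maximum
#' responsibility.
#'
#' @param summary clusters x genes matrix from
#'   [summarize_cluster_expression()] over the neuronal signature genes.
#' @param seed RNG seed for the EM restarts.
#' @return A `gmm_classification` with per-cluster labels
#'   `"neuronal"` / `"non-neuronal"`.
#' @export
classify_neuronal <- function(summary, seed = 0L) {
  summary <- as.matrix(summary)
  if (nrow(summary) < 3) stopf("need at least 3 clusters, have %d",
                               nrow(summary))
  fit <- fit_diag_gmm(summary, k = 2, seed = seed)
  norms <- sqrt(rowSums(fit$means^2))
  comp_names <- if (norms[1] >= norms[2]) {
    c("neuronal", "non-neuronal")
  } else {
    c("non-neuronal", "neuronal")
  }
  new_gmm_classification(fit, comp_names, summary, seed)
}

#' Three-class neurotransmitter classification of neuronal clusters
#'
#' Fits a three-component Gaussian mixture to per-cluster summaries of the
#' neurotransmitter signature genes (Slc17a6, Slc32a1, Gad1, Hdc). Components
#' are named by their mean expression profile: HA is the component with the
#' highest Hdc mean, GLUT the highest Slc17a6 mean among the remaining two,
#' GABA the last. A tie that would make the mapping ambiguous is an error.
#'
#' @param summary neuronal clusters x genes matrix; columns must include the
#'   Hdc-analog and Slc17a6-analog (positions 4 and 1 in the default
#'   signature order, matched by name when column names are present).
#' @param seed RNG seed.
#' @param glut_gene,hdc_gene column names identifying the class-defining
#'   genes (defaults `"Slc17a6"` and `"Hdc"`; positional fallback 1 and 4).
#' @return A `gmm_classification` with labels `"GLUT"`, `"GABA"`, `"HA"`.
#' @export
classify_neurotransmitter <- function(summary, seed = 0L,
                                      glut_gene = "Slc17a6",
                                      hdc_gene = "Hdc") {
  summary <- as.matrix(summary)
  if (nrow(summary) < 4) stopf("need at least 4 clusters, have %d",
                               nrow(summary))
  cn <- colnames(summary)
  gi <- if (!is.null(cn) && glut_gene %in% cn) match(glut_gene, cn) else 1L
  hi <- if (!is.null(cn) && hdc_gene %in% cn) match(hdc_gene, cn) else 4L
  fit <- fit_diag_gmm(summary, k = 3, seed = seed)
  hdc_means <- fit$means[, hi]
  if (sum(hdc_means == max(hdc_means)) > 1) {
    stopf("ambiguous HA mapping: component Hdc means are %s",
          paste(signif(hdc_means, 4), collapse = ", "))
  }
  ha <- which.max(hdc_means)
  rest <- setdiff(1:3, ha)
  glut_means <- fit$means[rest, gi]
  if (glut_means[1] == glut_means[2]) {
    stopf("ambiguous GLUT mapping: component %s means are both %s",
          glut_gene, signif(glut_means[1], 4))
  }
  glut <- rest[which.max(glut_means)]
  gaba <- setdiff(rest, glut)
  comp_names <- character(3)
  comp_names[c(ha, glut, gaba)] <- c("HA", "GLUT", "GABA")
  new_gmm_classification(fit, comp_names, summary, seed)
}

#' Classify individual cells under a fitted mixture
#'
#' Evaluates each cell's normalized expression of the signature genes under
#' the fitted mixture components and assigns the label of the maximum
#' posterior responsibility (ties to the lower component index).
#'
#' @param norm a `normalized_matrix`.
#' @param fitted a `gmm_classification` from [classify_neuronal()] or
#'   [classify_neurotransmitter()].
#' @param genes signature genes; defaults to the genes the model was fit on.
#' @return Character vector of per-cell class labels, named by cell id.
#' @export
classify_cells <- function(norm, fitted, genes = fitted$genes) {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(fitted, "gmm_classification"))
  X <- norm$values[, genes, drop = FALSE]
  n <- nrow(X)
  k <- nrow(fitted$means)
  lg <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lg[, j] <- log(fitted$weights[j]) +
      rowSums(dnorm(X, mean = matrix(fitted$means[j, ], n, ncol(X),
                                     byrow = TRUE),
                    sd = matrix(sqrt(fitted$vars[j, ]), n, ncol(X),
                                byrow = TRUE), log = TRUE))
  }
  comp <- max.col(lg, ties.method = "first")
  out <- fitted$component_names[comp]
  names(out) <- norm$cell_ids
  out
}
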