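rank1_norm <- function(n = 120, g = 30, noise = 1e-3, seed = 6) {
  set.seed(seed)
  u <- rnorm(n)
  v <- rnorm(g)
  vals <- outer(u, v) + matrix(rnorm(n * g, sd = noise), n, g)
  vals <- vals - min(vals)
  dimnames(vals) <- list(paste0("c", 1:n), paste0("g", 1:g))
  structure(list(values = vals, cell_ids = paste0("c", 1:n),
                 gene_ids = paste0("g", 1:g),
                 cell_meta = data.frame(row.names = paste0("c", 1:n)),
                 gene_meta = data.frame(row.names = paste0("g", 1:g))),
            class = "normalized_matrix")
}

test_that("PCA concentrates a rank-1 signal in the first component", {
  norm <- rank1_norm()
  emb <- compute_pcs(norm, norm$gene_ids, n_components = 5)
  expect_gt(emb$variance_ratio[1], 0.99)
  expect_true(all(diff(emb$variance_ratio) <= 1e-12))
  expect_true(all(emb$variance_ratio >= 0 & emb$variance_ratio <= 1))
  expect_lte(sum(emb$variance_ratio), 1 + 1e-12)

  # brute-force covariance eigendecomposition oracle
  centered <- scale(norm$values, scale = FALSE)
  ev <- eigen(cov(centered), symmetric = TRUE)
  expect_equal(abs(sum(emb$loadings[, 1] * ev$vectors[, 1])), 1,
               tolerance = 1e-6)
})

test_that("duplicating every cell leaves the component directions unchanged", {
  norm <- rank1_norm()
  dup <- norm
  dup$values <- rbind(norm$values, norm$values)
  dup$cell_ids <- c(norm$cell_ids, paste0(norm$cell_ids, "_d"))
  dup$cell_meta <- data.frame(row.names = dup$cell_ids)
  a <- compute_pcs(norm, norm$gene_ids, n_components = 3)
  b <- compute_pcs(dup, norm$gene_ids, n_components = 3)
  expect_equal(a$loadings, b$loadings, tolerance = 1e-6)
})

test_that("per-batch centering aligns constant-offset batches", {
  norm <- rank1_norm()
  emb <- compute_pcs(norm, norm$gene_ids, n_components = 4)
  batch <- rep(c("a", "b"), length.out = nrow(emb$coordinates))
  shifted <- emb
  shifted$coordinates[batch == "b", ] <-
    shifted$coordinates[batch == "b", ] + 5
  corr <- batch_correct(shifted, batch, method = "center")
  expect_true(corr$batch_corrected)
  ma <- colMeans(corr$coordinates[batch == "a", ])
  mb <- colMeans(corr$coordinates[batch == "b", ])
  expect_equal(ma, mb, tolerance = 1e-10)

  # a single batch just gets globally centered
  one <- batch_correct(emb, rep("x", nrow(emb$coordinates)), "center")
  expect_equal(colMeans(one$coordinates),
               rep(0, 4), tolerance = 1e-10, ignore_attr = TRUE)

  none <- batch_correct(emb, method = "none")
  expect_equal(none$coordinates, emb$coordinates)
  expect_false(none$batch_corrected)

  expect_warning(
    batch_correct(emb, c("solo", rep("x", nrow(emb$coordinates) - 1)),
                  "center"),
    "single cell")
  expect_error(batch_correct(emb, batch, "external"), "params\\$fun")
})

test_that("PC selection keeps the top variance ratios in original order", {
  norm <- rank1_norm(noise = 0.5)
  emb <- compute_pcs(norm, norm$gene_ids, n_components = 10)
  sel <- select_pcs(emb, 4)
  expect_equal(ncol(sel$coordinates), 4L)
  expect_equal(sel$variance_ratio, emb$variance_ratio[1:4])
  expect_equal(select_pcs(emb, 10)$coordinates, emb$coordinates)

  # unsorted ratios: selection is by magnitude, order preserved
  fake <- emb
  fake$variance_ratio <- c(0.1, 0.5, 0.2, 0.4, 0.3, 0.05, 0.04, 0.03,
                           0.02, 0.01)
  sel2 <- select_pcs(fake, 3)
  expect_equal(sel2$variance_ratio, c(0.5, 0.4, 0.3))
  expect_equal(colnames(sel2$coordinates), c("PC2", "PC4", "PC5"))
})

test_that("cosine distances hit their closed forms", {
  coords <- rbind(c(1, 0), c(2, 0), c(0, 3), c(-1, 0),
                  c(1, 1), c(4, 4), c(0.5, 0), c(0, 1),
                  c(3, 0), c(0, 2), c(1, 2), c(2, 1),
                  c(5, 5), c(6, 0), c(0, 6), c(2, 3))
  g <- build_knn(coords, k = 2)
  # parallel vectors (rows 1 and 2) are at distance 0
  expect_equal(g$nn_dist[1, 1], 0)
  expect_equal(g$nn_index[1, 1], 2L)
  d <- celltaxa:::cosine_distance_matrix(coords)
  expect_equal(d[1, 3], 1)   # orthogonal
  expect_equal(d[1, 4], 2)   # antiparallel
  expect_error(build_knn(coords[1:2, ], k = 2), "at least")
})

test_that("kNN matches an independent all-pairs search on a random fixture", {
  set.seed(13)
  coords <- matrix(rnorm(30 * 5), 30, 5)
  g <- build_knn(coords, k = 4)
  for (i in 1:30) {
    dists <- vapply(1:30, function(j) {
      1 - sum(coords[i, ] * coords[j, ]) /
        sqrt(sum(coords[i, ]^2) * sum(coords[j, ]^2))
    }, numeric(1))
    dists[i] <- Inf
    expect_equal(g$nn_index[i, ], order(dists, 1:30)[1:4])
  }
})
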