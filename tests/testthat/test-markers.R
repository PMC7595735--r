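fake_norm2 <- function(values, gene_ids = NULL) {
  gene_ids <- gene_ids %||% paste0("g", seq_len(ncol(values)))
  ids <- paste0("c", seq_len(nrow(values)))
  dimnames(values) <- list(ids, gene_ids)
  structure(list(values = values, cell_ids = ids, gene_ids = gene_ids,
                 cell_meta = data.frame(row.names = ids),
                 gene_meta = data.frame(row.names = gene_ids)),
            class = "normalized_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the mean-difference gate is strict at 2 log2 units", {
  v <- cbind(c(3, 3, 0.5, 0.5),     # diff 2.5: candidate
             c(3, 3, 1, 1),         # diff exactly 2: excluded
             c(1, 1, 1, 1))         # constant: excluded
  norm <- fake_norm2(v)
  lab <- c(0, 0, 1, 1)
  expect_equal(mean_diff_candidates(norm, lab, 0), "g1")
  expect_error(mean_diff_candidates(norm, rep(0, 4), 0), "every cell")
})

test_that("AUROC hits its closed forms", {
  expect_equal(auroc_score(c(5, 4, 3, 0, 1, 0), c(1, 1, 1, 0, 0, 0)), 1)
  expect_equal(auroc_score(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # pair enumeration: pairs (3,2),(3,0),(1,0) concordant, (1,2) discordant
  expect_equal(auroc_score(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc_score(1:3, c(1, 1, 1)), "nonempty")
})

test_that("rank-sum AUROC equals explicit ROC integration on 200 instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    n1 <- sample(seq_len(n - 1), 1)
    membership <- sample(c(rep(TRUE, n1), rep(FALSE, n - n1)))
    expr <- sample(0:5, n, replace = TRUE) +
      ifelse(runif(n) < 0.5, 0, 0.5)  # plenty of ties
    expect_equal(auroc_score(expr, membership),
                 auroc_by_integration(expr, membership),
                 tolerance = 1e-12)
  }
})

test_that("AUROC symmetry and rank invariance hold", {
  set.seed(98)
  for (i in 1:20) {
    expr <- sample(seq(0, 10, by = 0.01), 25)  # tie-free
    m <- sample(c(TRUE, FALSE), 25, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(m) || all(m)) next
    a <- auroc_score(expr, m)
    expect_equal(a + auroc_score(expr, !m), 1)
    expect_equal(auroc_score(exp(expr) + 3, m), a)  # monotone transform
  }
})

test_that("the marker table gates, sorts, and flags correctly", {
  set.seed(50)
  base <- matrix(abs(rnorm(40 * 6, 1, 0.1)), 40, 6)
  base[1:20, 1] <- base[1:20, 1] + 4    # marker of cluster 0
  base[21:40, 2] <- base[21:40, 2] + 3  # marker of cluster 1
  norm <- fake_norm2(base)
  lab <- rep(0:1, each = 20)
  tab <- rank_markers(norm, lab)
  expect_setequal(tab$gene[tab$cluster == 0], "g1")
  expect_setequal(tab$gene[tab$cluster == 1], "g2")
  expect_true(all(tab$pass == (tab$auroc > 0.8)))
  expect_true(all(tab$mean_diff > 2))
  # a uniform gene never appears
  expect_false("g3" %in% tab$gene)
  # tables of the two clusters are disjoint
  expect_length(intersect(tab$gene[tab$cluster == 0],
                          tab$gene[tab$cluster == 1]), 0)
})

test_that("planted markers pass the AUROC rule for their home cluster", {
  fix <- preset_norm()
  tab <- rank_markers(fix$norm, fix$true_cluster)
  mm <- fix$truth$marker_map
  hits <- vapply(seq_along(mm), function(c) {
    rows <- tab[tab$cluster == c & tab$gene %in% mm[[c]], ]
    sum(rows$pass)
  }, numeric(1))
  expect_gte(sum(hits) / (26 * 5), 0.95)
})

test_that("the Wilcoxon z matches stats::wilcox.test and ranks separators first", {
  set.seed(51)
  v <- matrix(rnorm(6 * 5, 2, 0.5), 6, 5)
  v[1:3, 2] <- v[1:3, 2] + 10  # perfect separator
  norm <- fake_norm2(v)
  lab <- c(0, 0, 0, 1, 1, 1)
  res <- wilcoxon_cross_check(norm, lab, 0)
  expect_equal(res$gene[1], "g2")
  expect_equal(max(abs(res$z)), abs(res$z[1]))
  # oracle: normal-approximation Wilcoxon p without continuity correction
  for (g in 1:5) {
    w <- suppressWarnings(
      wilcox.test(v[1:3, g], v[4:6, g], exact = FALSE, correct = FALSE))
    expect_equal(res$p[res$gene == paste0("g", g)], w$p.value,
                 tolerance = 1e-10)
  }
  expect_error(wilcoxon_cross_check(norm, c(0, rep(1, 5)), 0), "at least 2")
})

test_that("AUROC and Wilcoxon top-10 lists agree on planted markers", {
  fix <- preset_norm()
  tab <- rank_markers(fix$norm, fix$true_cluster, min_diff = 0)
  top_auroc <- head(tab$gene[tab$cluster == 1], 10)
  top_wilcox <- wilcoxon_cross_check(fix$norm, fix$true_cluster, 1,
                                     top_n = 10)$gene
  expect_gte(length(intersect(top_auroc, top_wilcox)), 8)
})

test_that("stratified splits are proportional, clamped, and seeded", {
  lab <- c(0, 0, 0, 0, 1, 1)
  s <- stratified_split(lab, 0.5, seed = 4)
  expect_equal(sum(lab[s$train] == 0), 2)
  expect_equal(sum(lab[s$train] == 1), 1)
  expect_setequal(c(s$train, s$test), 1:6)
  expect_length(intersect(s$train, s$test), 0)

  # odd cluster of 5 at fraction 0.5 splits 3/2 (half-up rounding)
  lab5 <- rep(0, 5)
  s5 <- stratified_split(c(lab5, 1, 1), 0.5, seed = 4)
  expect_equal(sum(c(lab5, 1, 1)[s5$train] == 0), 3)

  expect_identical(stratified_split(lab, 0.5, seed = 9),
                   stratified_split(lab, 0.5, seed = 9))
  expect_error(stratified_split(c(0, 0, 1), 0.5), "single cell")
})

test_that("panels union top-k genes and record shortfalls", {
  set.seed(52)
  v <- matrix(abs(rnorm(60 * 8, 1, 0.1)), 60, 8)
  lab <- rep(0:2, each = 20)
  v[lab == 0, 1:2] <- v[lab == 0, 1:2] + 4
  v[lab == 1, 3:4] <- v[lab == 1, 3:4] + 4
  v[lab == 2, 5:6] <- v[lab == 2, 5:6] + 4
  norm <- fake_norm2(v)
  panel <- top_k_panel(norm, lab, k = 2)
  expect_length(panel, 6)
  expect_false(any(attr(panel, "shortfall")))

  # clusters 0 and 1 share their single top marker: panel < k * K
  v2 <- matrix(abs(rnorm(60 * 3, 1, 0.1)), 60, 3)
  v2[lab %in% 0:1, 1] <- v2[lab %in% 0:1, 1] + 6
  v2[lab == 2, 2] <- v2[lab == 2, 2] + 6
  p2 <- top_k_panel(fake_norm2(v2), lab, k = 1)
  expect_setequal(p2, c("g1", "g2"))
  expect_lt(length(p2), 3)

  expect_length(top_k_panel(norm, lab, k = 0), 0)
})

test_that("shuffled labels drop sufficiency accuracy to chance", {
  fix <- preset_norm()
  set.seed(60)
  cells <- sample(nrow(fix$norm$values), 400)
  sub <- celltaxa:::subset_norm(fix$norm, cells)
  shuffled <- sample(rep_len(0:3, 400))
  res <- sufficiency_experiment(sub, shuffled, ks = 3, seed = 1,
                                min_diff = 0)
  chance <- max(table(shuffled)) / 400
  expect_lt(abs(res$results$accuracy[1] - chance), 0.05 + 0.05)
})

test_that("confusion matrices conserve test-set cluster sizes", {
  fix <- preset_norm()
  lab <- fix$true_cluster
  keep <- lab %in% 1:5
  sub <- celltaxa:::subset_norm(fix$norm, which(keep))
  res <- sufficiency_experiment(sub, lab[keep], ks = c(2, 5), seed = 2)
  split <- stratified_split(lab[keep], 0.5, seed = 2)
  test_sizes <- table(lab[keep][split$test])
  for (k in c("2", "5")) {
    expect_equal(as.vector(rowSums(res$confusion[[k]])),
                 as.vector(test_sizes))
  }
  # accuracy should not degrade as the panel grows (small noise allowed)
  expect_gte(res$results$accuracy[2], res$results$accuracy[1] - 0.02)
})
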