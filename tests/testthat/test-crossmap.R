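test_that("gene translation weights are bitscore-proportional and normalised", {
  ht <- homology_table(data.frame(
    gene_a = c("a1", "a2", "a2"), gene_b = c("b1", "b1", "b2"),
    bitscore = c(150, 100, 300)))
  tr <- build_gene_translation(ht, c("a1", "a2", "a3"), c("b1", "b2"))
  expect_equal(as.numeric(tr$ab["a1", ]), c(1, 0))
  expect_equal(as.numeric(tr$ab["a2", ]), c(0.25, 0.75))
  expect_equal(as.numeric(tr$ab["a3", ]), c(0, 0))
  rs <- Matrix::rowSums(tr$ab)
  expect_equal(unname(rs[rs > 0]), rep(1, 2), tolerance = 1e-12)
  rs_b <- Matrix::rowSums(tr$ba)
  expect_equal(unname(rs_b[rs_b > 0]), rep(1, 2), tolerance = 1e-12)
})

test_that("smoothing equals the explicit (D+I)^-1 (A+I) x operator", {
  # 5-node path graph via 1-d embedding
  emb <- cbind(c(0, 1, 2, 3, 4), 0)
  x <- matrix(c(2, 0, 4, 1, 3,
                7, 7, 7, 7, 7), ncol = 2)
  pm <- make_pm(x, embedding = emb, knn_k = 1)
  sm <- smooth_expression(pm)
  a <- as.matrix(igraph::as_adjacency_matrix(pm$knn$graph))
  a <- (a > 0) * 1
  w <- a + diag(5)
  oracle <- diag(1 / rowSums(w)) %*% w %*% as.matrix(pm$x)
  expect_equal(unname(sm), unname(oracle), tolerance = 1e-12)
  # constant gene stays constant; neighbourhood means preserve it exactly
  expect_equal(unname(sm[, 2]), rep(7, 5))
  # on a regular graph the global mean is preserved
  emb_c <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  pmr <- make_pm(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1), embedding = emb_c,
                 knn_k = 2)
  smr <- smooth_expression(pmr)
  expect_equal(mean(smr), mean(1:6), tolerance = 1e-12)
})

test_that("mapping a dataset against its own copy recovers identity", {
  sa <- small_analysis()
  pm <- sa$res$proc_a
  ident <- homology_table(data.frame(gene_a = colnames(pm$x),
                                     gene_b = colnames(pm$x),
                                     bitscore = 200))
  tr <- build_gene_translation(ident, colnames(pm$x), colnames(pm$x))
  jm <- joint_embed(pm, pm, tr, k_cross = 5)
  # each cell's nearest cross-neighbour is its own copy (distance 0)
  expect_true(mean(jm$ab$idx[, 1] == seq_len(nrow(pm$x))) > 0.95)
  self_first <- jm$ab$idx[, 1] == seq_len(nrow(pm$x))
  expect_lt(max(jm$ab$dist[self_first, 1]), 1e-4)
  al <- alignment_scores(jm, pm$clusters, pm$clusters)
  expect_true(all(al$pairs_a$cluster_a == al$pairs_a$best_b))
  # determinism
  jm2 <- joint_embed(pm, pm, tr, k_cross = 5)
  expect_identical(jm$ab$idx, jm2$ab$idx)
})

test_that("alignment scores saturate, vanish and respect label permutation", {
  fake_jm <- structure(list(
    z_a = matrix(0, 6, 2), z_b = matrix(0, 6, 2),
    ab = list(idx = matrix(rep(1:6, 2), 6, 2)),
    ba = list(idx = matrix(rep(1:6, 2), 6, 2))
  ), class = "JointMap")
  la <- c(1, 1, 1, 2, 2, 2)
  lb <- c(1, 1, 1, 2, 2, 2)
  # every cross-neighbour of cluster 1 lies in cluster 1 and vice versa
  al <- alignment_scores(fake_jm, la, lb)
  expect_equal(unname(al$scores["1", "1"]), 1)
  expect_equal(unname(al$scores["2", "2"]), 1)
  expect_equal(unname(al$scores["1", "2"]), 0)
  expect_true(all(al$scores >= 0 & al$scores <= 1))
  # permuting labels permutes rows/columns identically
  perm <- c(2, 1)
  al_p <- alignment_scores(fake_jm, perm[la], perm[lb])
  expect_equal(unname(al_p$scores[c("2", "1"), c("2", "1")]),
               unname(al$scores))
})

test_that("gene-pair correlation is symmetric, bounded and flags constants", {
  sa <- small_analysis()
  jm <- sa$res$jm
  tr <- sa$truth
  # within-pair correlation of a planted analog is strong and within [-1, 1]
  v <- gene_pair_correlation(jm, tr$analogs$gene_a[1], tr$analogs$gene_b[1])
  expect_true(v >= -1 && v <= 1)
  expect_gt(v, 0.2)
  expect_error(gene_pair_correlation(jm, "no_such_gene", tr$analogs$gene_b[1]),
               "unknown")
  # a constant gene yields a flagged NA, not silent zero
  pm_const <- jm$pm_a
  pm_const$x[, 1] <- 0
  jm_const <- jm
  jm_const$pm_a <- pm_const
  expect_warning(v0 <- gene_pair_correlation(jm_const, colnames(pm_const$x)[1],
                                             tr$analogs$gene_b[1]),
                 "undefined")
  expect_true(is.na(v0))
})

test_that("pair screening returns a subset of its universe with strict cut", {
  sa <- small_analysis()
  jm <- sa$res$jm
  hom <- small_dataset()$data$homology
  pairs <- find_gene_pairs(jm, hom, min_corr = 0.2, top_var = 60)
  expect_true(all(pairs$correlation > 0.2))
  tv_a <- analogmap:::top_variable_genes(jm$pm_a, 60)
  tv_b <- analogmap:::top_variable_genes(jm$pm_b, 60)
  hkey <- paste(hom$gene_a, hom$gene_b)
  in_universe <- paste(pairs$gene_a, pairs$gene_b) %in% hkey |
    (pairs$gene_a %in% tv_a & pairs$gene_b %in% tv_b)
  expect_true(all(in_universe))
  # inverse bitscore annotation: Inf exactly when no homology record exists
  has_rec <- paste(pairs$gene_a, pairs$gene_b) %in% hkey
  expect_true(all(is.infinite(pairs$inverse_bitscore[!has_rec])))
  expect_true(all(abs(pairs$inverse_bitscore[has_rec] -
                        1 / pairs$bitscore[has_rec]) < 1e-12))
  # the cut is strictly greater-than: raising it to an attained value drops it
  c0 <- pairs$correlation[1]
  pairs2 <- find_gene_pairs(jm, hom, min_corr = c0, top_var = 60)
  expect_false(any(abs(pairs2$correlation - c0) < 1e-15))
})
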