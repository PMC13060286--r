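test_that("QC removal predicates are strict at the documented boundaries", {
  # cells: mito exactly 0.30 (kept), mito 0.35 (removed), 750 counts (kept),
  # 749 counts (removed), low-feature cell (removed), healthy cell (kept)
  n_genes <- 300
  build_cell <- function(total, mito_frac, features) {
    mito_counts <- round(total * mito_frac)
    rest <- total - mito_counts
    per <- rest %/% (features - 1)
    extra <- rest - per * (features - 1)
    row <- numeric(n_genes)
    row[1] <- mito_counts
    row[2:features] <- per
    row[2] <- row[2] + extra
    row
  }
  m <- rbind(
    build_cell(1000, 0.30, 250),   # boundary mito: kept
    build_cell(1000, 0.35, 250),   # mito fail
    build_cell(750, 0, 250),       # boundary counts: kept
    build_cell(749, 0, 250),       # counts fail
    build_cell(1000, 0, 199),      # features fail
    build_cell(2000, 0.05, 280)    # healthy
  )
  cm <- make_cm(m, gene_ids = c("mt-g1", sprintf("g%03d", 2:n_genes)))
  cm$gene_meta$is_mito <- is_mito_gene(gene_ids(cm))
  out <- qc_filter(cm, pipeline_config())
  expect_setequal(out$removed, cell_ids(cm)[c(2, 4, 5)])
  expect_setequal(cell_ids(out$cm), cell_ids(cm)[c(1, 3, 6)])
  expect_equal(out$report$removed[out$report$criterion == "any"], 3)

  all_bad <- make_cm(matrix(1L, 2, 2), gene_ids = c("g1", "g2"))
  all_bad$gene_meta$is_mito <- c(FALSE, FALSE)
  expect_error(qc_filter(all_bad, pipeline_config()), "all")
})

test_that("QC removes exactly the planted violation set", {
  sd <- small_dataset()
  mats <- simulate_counts(sd$truth, sd$config, seed = 1)
  out <- qc_filter(mats$A, qc_preset("mouse"))
  expect_setequal(out$removed, sd$truth$qc_violations$A)
})

test_that("QC is monotone in its thresholds", {
  sd <- small_dataset()
  cm <- simulate_counts(sd$truth, sd$config, seed = 4)$A
  strict <- qc_filter(cm, pipeline_config(mito_max = 0.2, min_counts = 1000,
                                          min_features = 250))
  loose <- qc_filter(cm, pipeline_config(mito_max = 0.5, min_counts = 500,
                                         min_features = 100))
  expect_true(all(cell_ids(strict$cm) %in% cell_ids(loose$cm)))
})

test_that("log-normalisation scales each cell to the target sum", {
  m <- rbind(c(2, 2, 0, 0), c(1, 1, 1, 1), c(10, 0, 0, 0))
  cm <- make_cm(m)
  cm$gene_meta$is_mito <- rep(FALSE, 4)
  pm <- normalize_log(cm, scale = 1e4)
  expect_equal(as.numeric(pm$x[1, ]), log1p(c(5000, 5000, 0, 0)))
  # equal counts give identical normalised rows
  expect_equal(as.numeric(pm$x[2, ]), rep(log1p(2500), 4))
  # inverse transform recovers the scale
  resums <- Matrix::rowSums(expm1(as.matrix(pm$x)))
  expect_equal(resums, setNames(rep(1e4, 3), rownames(pm$x)), tolerance = 1e-8)

  zero <- make_cm(rbind(c(1, 1), c(0, 0)))
  expect_error(normalize_log(zero), "zero total")
})

test_that("highly variable gene selection flags dispersion, never constants", {
  set.seed(11)
  n <- 60
  x <- cbind(
    matrix(rnorm(n * 5, mean = 4, sd = 0.1), n, 5),   # quiet genes
    rep(c(0, 8), n / 2),                              # strongly bimodal
    matrix(rnorm(n * 2, mean = 4, sd = 0.1), n, 2),   # quiet genes
    matrix(3, n, 2)                                   # true constants
  )
  x <- pmax(x, 0)
  pm <- make_pm(x)
  pm <- select_hvg(pm, n_hvg = 1, n_mean_bins = 2)
  expect_equal(which(pm$hvg), c(g06 = 6L))
  expect_false(any(pm$hvg[9:10]))
  # requesting every gene flags all non-constant ones, with a warning
  expect_warning(pm2 <- select_hvg(pm, n_hvg = ncol(x), n_mean_bins = 2),
                 "non-constant")
  expect_equal(sum(pm2$hvg), 8)
  expect_false(any(pm2$hvg[9:10]))
})

test_that("PCA keeps the smallest component set reaching the variance target", {
  set.seed(2)
  base <- matrix(rnorm(40 * 2), 40, 2)
  x <- base %*% matrix(rnorm(2 * 10), 2, 10)   # exact rank 2
  pm <- make_pm(x + 5)
  pm$hvg <- setNames(rep(TRUE, 10), colnames(pm$x))
  pm <- embed_pca(pm, variance_target = 0.95, max_components = 10)
  expect_equal(ncol(pm$embedding), 2)
  expect_true(all(diff(pm$evr) <= 1e-12))
  expect_gte(sum(pm$evr[seq_len(ncol(pm$embedding))]), 0.95)
})

test_that("kNN graph matches brute-force geometry", {
  # three collinear points, k = 1: middle point joins its nearer endpoint
  emb <- cbind(c(0, 1, 3), 0)
  pm <- make_pm(matrix(rpois(9, 4), 3, 3), embedding = emb, knn_k = 1)
  g <- pm$knn$graph
  expect_true(igraph::are_adjacent(g, 1, 2))
  expect_false(igraph::are_adjacent(g, 2, 3) && !igraph::are_adjacent(g, 1, 2))
  expect_equal(pm$knn$idx[2, 1], 1L)   # middle point's nearest is the closer end

  set.seed(5)
  emb <- matrix(rnorm(50 * 4), 50, 4)
  pm <- make_pm(matrix(rpois(50 * 3, 4), 50, 3), embedding = emb, knn_k = 6)
  d <- as.matrix(dist(emb))
  for (i in seq_len(50)) {
    expected <- order(d[i, -i])[1:6]
    expected <- setdiff(order(d[i, ]), i)[1:6]
    expect_setequal(pm$knn$idx[i, ], expected)
  }
  deg <- igraph::degree(pm$knn$graph)
  expect_true(all(deg >= 6))
  expect_equal(sum(igraph::which_loop(pm$knn$graph)), 0)
})

test_that("community detection recovers separated blobs deterministically", {
  set.seed(9)
  emb <- rbind(matrix(rnorm(40 * 2, 0), 40, 2),
               matrix(rnorm(40 * 2, 12), 40, 2))
  pm <- make_pm(matrix(rpois(80 * 3, 4), 80, 3), embedding = emb, knn_k = 15)
  pm1 <- cluster_cells(pm, resolution = 0.5, seed = 0)
  expect_equal(length(unique(pm1$clusters)), 2)
  expect_equal(adjusted_rand(pm1$clusters, rep(1:2, each = 40)), 1)
  pm2 <- cluster_cells(pm, resolution = 0.5, seed = 0)
  expect_identical(pm1$clusters, pm2$clusters)
  # a single tight clique collapses to one community
  emb1 <- matrix(rnorm(20 * 2, 0, 0.1), 20, 2)
  pmc <- make_pm(matrix(rpois(60, 4), 20, 3), embedding = emb1, knn_k = 19)
  pmc <- cluster_cells(pmc, resolution = 0.5, seed = 0)
  expect_equal(length(unique(pmc$clusters)), 1)
})

test_that("wilcoxon markers: extreme separation gives U = n1*n2 and tiny p", {
  x <- matrix(c(5, 6, 7, 1, 2, 3, 0, 1,    # gene separating cluster 1
                4, 4, 4, 4, 4, 4, 4, 4),   # flat gene
              ncol = 2)
  pm <- make_pm(x, clusters = c(1, 1, 1, 2, 2, 2, 2, 2))
  mt <- rank_markers_wilcoxon(pm)
  rec <- mt[mt$cluster == 1 & mt$gene == "g01", ]
  expect_equal(rec$u_statistic, 3 * 5)
  expect_lt(rec$p_value, 0.05)
  expect_gt(rec$log_fold_change, 0)
  # BH adjustment is monotone in p within each cluster
  for (cl in unique(mt$cluster)) {
    sub <- mt[mt$cluster == cl, ]
    ord <- order(sub$p_value)
    expect_true(all(diff(sub$adjusted_p[ord]) >= -1e-12))
    expect_true(all(sub$adjusted_p >= sub$p_value - 1e-12))
  }
})

test_that("composition proportions equal exhaustive tallies", {
  meta <- data.frame(region = c("d", "d", "d", "p", "p"),
                     label = c("a", "a", "b", "b", "b"))
  tab <- composition(meta, "region", "label")
  expect_equal(tab$proportion[tab$group == "d" & tab$label == "a"], 2 / 3)
  expect_equal(tab$proportion[tab$group == "d" & tab$label == "b"], 1 / 3)
  sums <- tapply(tab$proportion, tab$group, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
  # counting oracle
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$n[i], sum(meta$region == tab$group[i] &
                                 meta$label == tab$label[i]))
  }
  expect_error(composition(meta, "region", "missing_col"), "missing_col")
})
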