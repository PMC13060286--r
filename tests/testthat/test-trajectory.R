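test_that("pseudotime is zero at the root and ordered along a chain", {
  emb <- cbind(0:9, 0)
  pm <- make_pm(matrix(rpois(10 * 3, 4), 10, 3), embedding = emb, knn_k = 1)
  pm$clusters <- setNames(c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2), rownames(pm$x))
  traj <- compute_pseudotime(pm, root_clusters = 1, smooth_rounds = 0)
  expect_equal(unname(traj$t_raw[traj$root_cell]), 0)
  # chain order: geodesic distance increases monotonically from cell 2 outwards
  root_idx <- match(traj$root_cell, rownames(pm$x))
  expect_equal(root_idx, 2)   # medoid of cells 1..3 on a line
  expect_true(all(diff(traj$t_raw[2:10]) > 0))
  expect_equal(order(traj$t_raw[3:10]), 1:8)   # shortest-path oracle on a path
})

test_that("branch signing follows the documented rule", {
  emb <- cbind(c(0, 1, 2, -1, -2), 0)
  pm <- make_pm(matrix(rpois(15, 4), 5, 3), embedding = emb, knn_k = 1)
  pm$clusters <- setNames(c(1, 2, 2, 3, 3), rownames(pm$x))
  traj <- compute_pseudotime(pm, root_clusters = 1, smooth_rounds = 0)
  bm <- c("1" = "progenitor", "2" = "ciliogenic", "3" = "secretory")
  traj <- assign_branches(traj, pm, bm)
  expect_true(all(traj$signed[pm$clusters == 2] >= 0))
  expect_true(all(traj$signed[pm$clusters == 3] <= 0))
  expect_equal(max(abs(traj$signed)), 1)
  # secretory cell at scaled t has signed -t, ciliogenic +t
  expect_equal(unname(traj$signed[pm$clusters == 3]),
               -unname(traj$pseudotime[pm$clusters == 3]))
  # progenitor root takes the sign of its nearest non-progenitor neighbour
  expect_true(traj$branch_side[1] %in% c("secretory", "ciliogenic"))
  expect_error(assign_branches(traj, pm, bm[-1]), "missing")
})

test_that("equal-count binning is balanced, ordered and deterministic", {
  set.seed(3)
  s80 <- setNames(runif(80, -1, 1), sprintf("c%03d", 1:80))
  b80 <- bin_pseudotime(s80, n_bins = 40)
  expect_equal(as.integer(table(b80)), rep(2L, 40))

  s81 <- c(s80, c081 = 0.5)
  b81 <- bin_pseudotime(s81, n_bins = 40)
  sizes <- as.integer(table(b81))
  expect_setequal(unique(sizes), c(2L, 3L))
  expect_equal(sum(sizes == 3L), 1)
  expect_equal(sum(sizes), 81)

  # sort oracle: max signed in bin i never exceeds min in bin i+1
  for (i in 1:39) {
    expect_lte(max(s81[b81 == i]), min(s81[b81 == i + 1]))
  }
  expect_identical(b81, bin_pseudotime(s81, n_bins = 40))
  expect_error(bin_pseudotime(s80[1:10], n_bins = 40), "exceeds")
})

test_that("bin trends equal a group-mean oracle and centre to zero", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                rep(4, 10),
                10:1), ncol = 3)
  pm <- make_pm(x)
  signed <- setNames(seq(-1, 1, length.out = 10), rownames(pm$x))
  bins <- bin_pseudotime(signed, n_bins = 5)
  tr <- bin_expression_trends(pm, bins)
  # constant gene: all-zero trend
  expect_equal(unname(tr[, 2]), rep(0, 5))
  # explicit z-score + group mean oracle for gene 1
  z <- (x[, 1] - mean(x[, 1])) / sd(x[, 1])
  oracle <- tapply(z, bins, mean)
  expect_equal(unname(tr[, 1]), as.numeric(oracle[rownames(tr)]),
               tolerance = 1e-12)
  # cell-count-weighted mean of each gene trend is zero
  w <- as.integer(table(bins))
  for (g in 1:3) {
    expect_lt(abs(sum(tr[, g] * w) / sum(w)), 1e-12)
  }
  # invariance to cell order permutation
  perm <- sample(10)
  pm_p <- make_pm(x[perm, , drop = FALSE],
                  clusters = NULL)
  rownames(pm_p$x) <- rownames(pm$x)[perm]
  tr_p <- bin_expression_trends(pm_p, bins[rownames(pm_p$x)])
  expect_equal(tr_p, tr, tolerance = 1e-12)
})

test_that("signature scores follow the rank-sum definition and its extremes", {
  n_genes <- 20
  r_max <- 15
  x <- rbind(c(n_genes:1),              # signature genes top-ranked
             rep(1, n_genes),           # all tied
             c(1:n_genes))              # signature genes bottom-ranked
  colnames(x) <- sprintf("g%02d", 1:n_genes)
  pm <- make_pm(x)
  sig <- c("g01", "g02", "g03")
  sc <- score_signature(pm, sig, r_max = r_max)
  ns <- 3
  # cell 1: signature occupies the top ns ranks -> maximal score
  expect_equal(unname(sc[1]), 1 - (sum(1:ns) - ns * (ns + 1) / 2) / (ns * r_max))
  expect_equal(unname(sc[1]), 1)
  # cell 3: signature ranked past the cap -> the documented minimum
  expect_equal(unname(sc[3]), (ns + 1) / (2 * r_max), tolerance = 1e-12)
  # explicit rank oracle for every cell
  for (i in 1:3) {
    rk <- pmin(rank(-x[i, ], ties.method = "average"), r_max)
    u <- sum(rk[match(sig, colnames(x))]) - ns * (ns + 1) / 2
    expect_equal(unname(sc[i]), 1 - u / (ns * r_max), tolerance = 1e-12)
  }
  expect_error(score_signature(pm, character(0)), "empty")
  expect_warning(score_signature(pm, c(sig, "nope"), r_max = r_max), "unknown")
  expect_error(score_signature(pm, colnames(x), r_max = 10), "rank cap")
})

test_that("trajectory recovery on synthetic data tracks latent time", {
  sa <- small_analysis()
  res <- sa$res
  pm <- res$proc_a
  tj <- res$traj_a
  keep <- pm$cell_meta$true_state %in%
    c("progenitor", "secretory", "pre_ciliated", "ciliated")
  for (b in c("secretory", "ciliogenic")) {
    sel <- keep & pm$cell_meta$true_branch == b & tj$branch_side == b
    rho <- cor(tj$pseudotime[sel], pm$cell_meta$true_time[sel],
               method = "spearman")
    expect_gt(abs(rho), 0.8)
  }
  sel <- pm$cell_meta$true_state %in% c("secretory", "pre_ciliated", "ciliated")
  expect_gt(mean(tj$branch_side[sel] == pm$cell_meta$true_branch[sel]), 0.9)
})

test_that("the early-to-late ciliogenic handoff crosses exactly once", {
  da <- default_analysis()
  for (sp in c("A", "B")) {
    tj <- if (sp == "A") da$res$traj_a else da$res$traj_b
    ho <- da$truth$handoff[[sp]]
    pos <- tj$bin_table$bin[tj$bin_table$mean_signed > 0]
    d <- tj$trends[as.character(pos), ho[["early"]]] -
      tj$trends[as.character(pos), ho[["late"]]]
    sgn <- sign(d)
    sgn <- sgn[sgn != 0]
    expect_equal(sum(diff(sgn) != 0), 1)
  }
})
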