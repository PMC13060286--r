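test_that("top state markers are positive-FC, ordered and prefix-stable", {
  mt <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    cluster = 1,
    log_fold_change = c(2, 1.5, -1, 0.5, 3),
    u_statistic = 0,
    p_value = c(1e-8, 1e-6, 1e-9, 1e-4, 1e-8),
    adjusted_p = c(1e-7, 1e-5, 1e-8, 1e-3, 1e-7)
  )
  class(mt) <- c("MarkerTable", "data.frame")
  top <- suppressWarnings(top_state_markers(mt, n_top = 3))
  # negative-FC gene g3 excluded; ties on adjusted p broken by FC
  expect_equal(top[["1"]], c("g5", "g1", "g2"))
  top2 <- suppressWarnings(top_state_markers(mt, n_top = 2))
  expect_equal(top2[["1"]], top[["1"]][1:2])
  only_one <- mt[mt$gene == "g1", ]
  class(only_one) <- c("MarkerTable", "data.frame")
  expect_warning(t1 <- top_state_markers(only_one, n_top = 5), "only")
  expect_equal(t1[["1"]], "g1")
})

test_that("conservation classifier recovers the planted structure", {
  sa <- small_analysis()
  res <- sa$res
  truth <- sa$truth
  cons <- res$conservation
  expect_s3_class(cons, "ConservationReference")
  expect_true(all(cons$class %in% c("conserved", "a_specific", "b_specific")))
  expect_true(all(cons$correlation[cons$class == "conserved"] > 0.2))
  # disjointness of the three lists per state
  for (s in unique(cons$state)) {
    sub <- cons[cons$state == s, ]
    ca <- sub$gene_a[sub$class == "conserved"]
    cb <- sub$gene_b[sub$class == "conserved"]
    expect_length(intersect(ca, sub$gene_a[sub$class == "a_specific"]), 0)
    expect_length(intersect(cb, sub$gene_b[sub$class == "b_specific"]), 0)
  }
  # planted markers that enter the reference are classified correctly
  planted_cons <- unlist(lapply(truth$markers, function(m) m$conserved$gene_a))
  planted_spec <- unlist(lapply(truth$markers, function(m) m$a_specific))
  judged_cons <- intersect(cons$gene_a[cons$class == "conserved"],
                           c(planted_cons, planted_spec))
  judged_spec <- intersect(cons$gene_a[cons$class == "a_specific"],
                           c(planted_cons, planted_spec))
  expect_gt(mean(judged_cons %in% planted_cons), 0.8)
  expect_gt(mean(judged_spec %in% planted_spec), 0.8)
})

test_that("markers without any ortholog are species-specific with null score", {
  sa <- small_analysis()
  jm <- sa$res$jm
  hom <- small_dataset()$data$homology
  orphan <- setdiff(colnames(jm$pm_a$x), hom$gene_a)[1]
  partnered <- sa$truth$markers$progenitor$conserved
  sm_a <- list(progenitor = c(orphan, partnered$gene_a[1]))
  sm_b <- list(progenitor = partnered$gene_b[1])
  ref <- classify_conservation(sm_a, sm_b, hom, jm, threshold = 0.2)
  orow <- ref[!is.na(ref$gene_a) & ref$gene_a == orphan, ]
  expect_equal(orow$class, "a_specific")
  expect_true(is.na(orow$correlation))
  # a strongly correlated ortholog pair lands in the conserved list
  crow <- ref[!is.na(ref$gene_a) & ref$gene_a == partnered$gene_a[1], ]
  expect_equal(crow$class[1], "conserved")
  expect_equal(crow$gene_b[1], partnered$gene_b[1])
})

test_that("swapping the species swaps the specific lists exactly", {
  sa <- small_analysis()
  res <- sa$res
  hom <- small_dataset()$data$homology
  hom_sw <- homology_table(data.frame(gene_a = hom$gene_b, gene_b = hom$gene_a,
                                      bitscore = hom$bitscore))
  tr_sw <- build_gene_translation(hom_sw, colnames(res$proc_b$x),
                                  colnames(res$proc_a$x))
  jm_sw <- joint_embed(res$proc_b, res$proc_a, tr_sw, k_cross = 20)
  sm_a <- res$state_markers_a["progenitor"]
  sm_b <- res$state_markers_b["progenitor"]
  fwd <- classify_conservation(sm_a, sm_b, hom, res$jm, threshold = 0.2)
  rev <- classify_conservation(sm_b, sm_a, hom_sw, jm_sw, threshold = 0.2)
  expect_setequal(fwd$gene_a[fwd$class == "a_specific"],
                  rev$gene_b[rev$class == "b_specific"])
  expect_setequal(fwd$gene_b[fwd$class == "b_specific"],
                  rev$gene_a[rev$class == "a_specific"])
})

test_that("category scores equal the two-step mean/z oracle", {
  # 3 states x 4 genes hand fixture: 6 cells, 2 per state
  x <- rbind(c(10, 0, 1, 2), c(8, 0, 1, 2),
             c(0, 6, 1, 4), c(0, 4, 1, 4),
             c(0, 0, 1, 9), c(0, 2, 1, 9))
  pm <- make_pm(x)
  states <- c("s1", "s1", "s2", "s2", "s3", "s3")
  map <- data.frame(gene = c("g01", "g02", "g03", "g04", "g05"),
                    category = c("catA", "catA", "catB", "catB", "catC"))
  expect_warning(sc <- category_scores(pm, states, map), "catC")
  expect_equal(colnames(sc), c("catA", "catB"))
  # oracle: per-gene state means, z across states, category mean
  sm <- apply(x, 2, function(g) tapply(g, states, mean))
  z <- scale(sm)
  z[!is.finite(z)] <- 0
  expect_equal(unname(sc[, "catA"]), unname(rowMeans(z[, 1:2])),
               tolerance = 1e-12)
  expect_equal(unname(sc[, "catB"]), unname(rowMeans(z[, 3:4])),
               tolerance = 1e-12)
  # single-gene category expressed only in one state peaks there
  map1 <- data.frame(gene = "g01", category = "solo")
  sc1 <- category_scores(pm, states, map1)
  expect_equal(rownames(sc1)[which.max(sc1[, "solo"])], "s1")
  # per-gene contributions centre to ~0 across states
  expect_lt(abs(sum(z[, 1])), 1e-12)
})
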