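#' Quality-control filtering of cells
#'
#' Removes cells whose mitochondrial count fraction exceeds `mito_max`, whose
#' total counts fall below `min_counts`, or whose number of detected genes
#' falls below `min_features`. All inequalities are strict ("greater than" /
#' "fewer than"): a cell at exactly the mitochondrial ceiling or exactly the
#' count floor is kept.
#'
#' @param cm a [count_matrix()] with `gene_meta$is_mito` populated.
#' @param config a [pipeline_config()] (or [qc_preset()]).
#' @return list with `cm` (the filtered `CountMatrix`, whose `cell_meta`
#'   gains `n_counts`, `n_features`, `mito_fraction`) and `report` (a data
#'   frame of per-criterion and total removal counts).
#' @export
qc_filter <- function(cm, config = pipeline_config()) {
  if (is.null(cm$gene_meta$is_mito)) {
    stopf("gene_meta$is_mito must be populated before QC")
  }
  counts <- cm$counts
  n_counts <- Matrix::rowSums(counts)
  n_feat <- Matrix::rowSums(counts > 0)
  mito <- Matrix::rowSums(counts[, cm$gene_meta$is_mito, drop = FALSE])
  mito_frac <- ifelse(n_counts > 0, mito / n_counts, 0)
  fail_mito <- mito_frac > config$mito_max
  fail_counts <- n_counts < config$min_counts
  fail_feat <- n_feat < config$min_features
  fail <- fail_mito | fail_counts | fail_feat
  if (all(fail)) stopf("QC removed all %d cells; check thresholds", nrow(counts))
  report <- data.frame(
    criterion = c("mito_fraction", "min_counts", "min_features", "any"),
    threshold = c(config$mito_max, config$min_counts, config$min_features, NA),
    removed = c(sum(fail_mito), sum(fail_counts), sum(fail_feat), sum(fail))
  )
  cm$cell_meta$n_counts <- n_counts
  cm$cell_meta$n_features <- n_feat
  cm$cell_meta$mito_fraction <- mito_frac
  kept <- subset_cells(cm, cells = which(!fail))
  am_log("info", "QC removed %d/%d cells (mito %d, counts %d, features %d)",
         sum(fail), nrow(counts), sum(fail_mito), sum(fail_counts), sum(fail_feat))
  list(cm = kept, report = report,
       removed = cell_ids(cm)[fail])
}

#' Library-size normalisation and log transform
#'
#' Scales each cell to `scale` total counts and applies `log(1 + x)`, the
#' standard single-cell log-normalisation.
#'
#' @param cm a `CountMatrix` (post-QC: no zero-total cells).
#' @param scale target per-cell sum before the log, default 1e4.
#' @return an object of class `ProcessedMatrix`: a list with `x` (sparse
#'   log-normalised cells x genes matrix), `cell_meta`, `gene_meta`; later
#'   stages append `hvg`, `embedding`, `evr`, `knn`, `clusters`.
#' @export
normalize_log <- function(cm, scale = 1e4) {
  tot <- Matrix::rowSums(cm$counts)
  if (any(tot == 0)) {
    stopf("cell(s) with zero total counts: %s",
          paste(head(cell_ids(cm)[tot == 0], 5), collapse = ", "))
  }
  x <- Matrix::Diagonal(x = scale / tot) %*% cm$counts
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(cm$counts)
  structure(list(x = methods::as(x, "CsparseMatrix"),
                 cell_meta = cm$cell_meta, gene_meta = cm$gene_meta),
            class = "ProcessedMatrix")
}

#' @export
print.ProcessedMatrix <- function(x, ...) {
  cat(sprintf("ProcessedMatrix: %d cells x %d genes\n", nrow(x$x), ncol(x$x)))
  if (!is.null(x$hvg)) cat(sprintf("  %d highly variable genes\n", sum(x$hvg)))
  if (!is.null(x$embedding)) {
    cat(sprintf("  embedding: %d components\n", ncol(x$embedding)))
  }
  if (!is.null(x$clusters)) {
    cat(sprintf("  %d clusters\n", length(unique(x$clusters))))
  }
  invisible(x)
}

col_stats <- function(x) {
  mu <- Matrix::colSums(x) / nrow(x)
  ex2 <- Matrix::colSums(x^2) / nrow(x)
  v <- (ex2 - mu^2) * nrow(x) / max(1, nrow(x) - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Select highly variable genes
#'
#' Dispersion (variance / mean of log-normalised expression) is standardised
#' within 20 equal-occupancy mean bins (z-score of dispersion against the
#' gene's mean-expression peers) and the `n_hvg` genes with the largest
#' standardised dispersion are flagged. Ties break by gene id so the
#' selection is deterministic. Constant genes are never flagged; if fewer
#' than `n_hvg` non-constant genes exist, all of them are flagged with a
#' warning.
#'
#' @param pm a `ProcessedMatrix`.
#' @param n_hvg number of genes to flag.
#' @param n_mean_bins number of mean-expression bins, default 20.
#' @return `pm` with logical `hvg` (named by gene) set.
#' @export
select_hvg <- function(pm, n_hvg = 2000, n_mean_bins = 20) {
  st <- col_stats(pm$x)
  nonconst <- st$var > 1e-12
  disp <- ifelse(st$mean > 0, st$var / pmax(st$mean, 1e-12), 0)
  score <- rep(-Inf, ncol(pm$x))
  idx <- which(nonconst)
  if (length(idx)) {
    br <- unique(quantile(st$mean[idx], probs = seq(0, 1, length.out = n_mean_bins + 1)))
    bin <- cut(st$mean[idx], breaks = br, include.lowest = TRUE)
    z <- disp[idx]
    for (b in levels(bin)) {
      sel <- bin == b
      m <- mean(z[sel]); s <- sd(z[sel])
      z[sel] <- if (is.na(s) || s < 1e-12) 0 else (z[sel] - m) / s
    }
    score[idx] <- z
  }
  n_avail <- sum(nonconst)
  if (n_avail < n_hvg) {
    warnf("only %d non-constant genes available for %d requested HVGs; flagging all",
          n_avail, n_hvg)
    n_hvg <- n_avail
  }
  ord <- order(-score, colnames(pm$x))
  hvg <- rep(FALSE, ncol(pm$x))
  hvg[ord[seq_len(n_hvg)]] <- TRUE
  hvg <- hvg & nonconst
  names(hvg) <- colnames(pm$x)
  pm$hvg <- hvg
  pm
}

#' Principal-component embedding
#'
#' Expression of the highly variable genes is z-scored per gene and
#' decomposed by PCA (up to `max_components` components). The smallest
#' number of leading components whose cumulative share of the computed
#' components' variance reaches `variance_target` is kept (at least one).
#'
#' @param pm a `ProcessedMatrix` with `hvg` set.
#' @param variance_target cumulative explained-variance target, default 0.95.
#' @param max_components maximum components computed, default 100.
#' @return `pm` with `embedding` (cells x m) and `evr` (per-component
#'   explained-variance ratios over the computed components).
#' @export
embed_pca <- function(pm, variance_target = 0.95, max_components = 100) {
  if (is.null(pm$hvg)) stopf("run select_hvg() before embed_pca()")
  x <- as.matrix(pm$x[, pm$hvg, drop = FALSE])
  x <- base::scale(x)
  x[!is.finite(x)] <- 0
  rank <- min(max_components, dim(x) - 1)
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = rank)
  vars <- pc$sdev[seq_len(min(rank, length(pc$sdev)))]^2
  evr <- vars / sum(vars)
  m <- which(cumsum(evr) >= variance_target)[1]
  if (is.na(m) || m < 1) m <- length(evr)
  m <- max(1L, m)
  emb <- pc$x[, seq_len(m), drop = FALSE]
  rownames(emb) <- rownames(pm$x)
  pm$embedding <- emb
  pm$evr <- evr
  am_log("info", "PCA kept %d/%d components (%.1f%% of computed variance)",
         m, length(evr), 100 * sum(evr[seq_len(m)]))
  pm
}

# exact k nearest neighbours by blocked pairwise Euclidean distances
knn_brute <- function(emb, k, query = emb, self = TRUE, block = 512L) {
  n <- nrow(emb); nq <- nrow(query)
  if (k >= n + !self) stopf("k = %d must be smaller than the number of cells (%d)", k, n)
  nn_idx <- matrix(0L, nq, k)
  nn_dist <- matrix(0, nq, k)
  cn2 <- rowSums(emb^2)
  for (start in seq(1, nq, by = block)) {
    rows <- start:min(nq, start + block - 1)
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), cn2, "+") - 2 * tcrossprod(q, emb)
    d2[d2 < 0] <- 0
    for (r in seq_along(rows)) {
      d <- d2[r, ]
      if (self) d[rows[r]] <- Inf
      ord <- order(d)[seq_len(k)]
      nn_idx[rows[r], ] <- ord
      nn_dist[rows[r], ] <- sqrt(d[ord])
    }
  }
  list(idx = nn_idx, dist = nn_dist)
}

#' Build a symmetrised k-nearest-neighbour graph
#'
#' Exact Euclidean k nearest neighbours in embedding space, symmetrised by
#' edge union; edges are weighted by distance; no self loops.
#'
#' @param pm a `ProcessedMatrix` with `embedding` set.
#' @param k number of neighbours (default 70).
#' @return `pm` with `knn`, a list of `graph` (an `igraph` with `weight` =
#'   distance), `idx` and `dist` (the raw directed neighbour matrices).
#' @export
build_knn <- function(pm, k = 70) {
  if (is.null(pm$embedding)) stopf("run embed_pca() before build_knn()")
  nn <- knn_brute(pm$embedding, k)
  n <- nrow(pm$embedding)
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nn$idx)))
  w <- as.vector(t(nn$dist))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  igraph::V(g)$name <- rownames(pm$embedding)
  pm$knn <- list(graph = g, idx = nn$idx, dist = nn$dist, k = k)
  pm
}

#' Graph community detection
#'
#' Louvain modularity optimisation at the given resolution with a fixed
#' seed; the unweighted symmetrised kNN graph is used, and labels are
#' relabelled as consecutive integers 1, 2, ... ordered by decreasing
#' cluster size for cross-run comparability.
#'
#' @param pm a `ProcessedMatrix` with `knn` set.
#' @param resolution modularity resolution, default 0.7.
#' @param seed RNG seed for the community detection.
#' @return `pm` with integer `clusters` (named by cell).
#' @export
cluster_cells <- function(pm, resolution = 0.7, seed = 0L) {
  if (is.null(pm$knn)) stopf("run build_knn() before cluster_cells()")
  g <- pm$knn$graph
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, weights = NA, resolution = resolution)
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  lab <- as.integer(relabel[as.character(raw)])
  names(lab) <- rownames(pm$x)
  pm$clusters <- lab
  am_log("info", "found %d clusters at resolution %.2f", length(sizes), resolution)
  pm
}

# column-wise ranks of a dense matrix (average rank for ties)
col_ranks <- function(x) apply(x, 2, rank, ties.method = "average")

#' One-vs-rest Wilcoxon rank-sum marker detection
#'
#' For each cluster and gene, a two-sided Wilcoxon rank-sum (Mann-Whitney U)
#' test of the cluster's cells against all other cells, using the normal
#' approximation with tie correction. Log2 fold changes are computed on
#' `expm1`-transformed means with a pseudocount, and p-values are
#' Benjamini-Hochberg adjusted within each cluster's gene family.
#'
#' @param pm a `ProcessedMatrix` with `clusters` set.
#' @param pseudocount added to both means before the ratio, default 1e-9.
#' @return a `MarkerTable` data frame with columns `gene`, `cluster`,
#'   `log_fold_change`, `u_statistic`, `p_value`, `adjusted_p`.
#' @export
rank_markers_wilcoxon <- function(pm, pseudocount = 1e-9) {
  if (is.null(pm$clusters)) stopf("run cluster_cells() before marker detection")
  labs <- pm$clusters
  if (length(unique(labs)) < 2) stopf("marker detection needs >= 2 clusters")
  x <- as.matrix(pm$x)
  n <- nrow(x)
  rk <- col_ranks(x)
  # tie correction term per gene: sum over tied groups of (t^3 - t)
  tie_term <- apply(x, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })
  res <- list()
  for (cl in sort(unique(labs))) {
    in_cl <- labs == cl
    n1 <- sum(in_cl); n2 <- n - n1
    if (n1 < 2) {
      warnf("cluster %s has fewer than 2 cells; skipped", cl)
      next
    }
    r1 <- colSums(rk[in_cl, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu_u <- n1 * n2 / 2
    sig2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    sig <- sqrt(pmax(sig2, 0))
    z <- ifelse(sig > 0, (u - mu_u) / sig, 0)
    p <- 2 * pnorm(-abs(z))
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    m_in <- colMeans(expm1(x[in_cl, , drop = FALSE]))
    m_out <- colMeans(expm1(x[!in_cl, , drop = FALSE]))
    lfc <- log2((m_in + pseudocount) / (m_out + pseudocount))
    res[[as.character(cl)]] <- data.frame(
      gene = colnames(x), cluster = cl, log_fold_change = lfc,
      u_statistic = u, p_value = p,
      adjusted_p = p.adjust(p, method = "BH"),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' Per-group label composition
#'
#' @param cell_meta a data frame of cell annotations.
#' @param group_col,label_col column names in `cell_meta`.
#' @return data frame `group`, `label`, `n`, `proportion`; proportions sum to
#'   1 within each group.
#' @export
composition <- function(cell_meta, group_col, label_col) {
  for (col in c(group_col, label_col)) {
    if (!col %in% names(cell_meta)) stopf("column '%s' not found", col)
  }
  g <- as.character(cell_meta[[group_col]])
  l <- as.character(cell_meta[[label_col]])
  if (!length(g)) stopf("empty cell metadata")
  tab <- as.data.frame(table(group = g, label = l), stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0 | TRUE, ]
  tot <- tapply(tab$n, tab$group, sum)
  if (any(tot == 0)) stopf("empty group: %s", names(tot)[tot == 0][1])
  tab$proportion <- tab$n / tot[tab$group]
  tab <- tab[order(tab$group, tab$label), ]
  rownames(tab) <- NULL
  tab
}

#' Run the per-species processing chain
#'
#' Convenience wrapper: QC, log-normalisation, HVG selection, PCA, kNN graph
#' and clustering with one configuration.
#'
#' @param cm a `CountMatrix`.
#' @param config a [pipeline_config()].
#' @return list with `pm` (fully populated `ProcessedMatrix`), `qc_report`,
#'   `removed` (QC-removed cell ids).
#' @export
process_species <- function(cm, config = pipeline_config()) {
  qc <- qc_filter(cm, config)
  pm <- normalize_log(qc$cm, scale = config$scale)
  pm <- select_hvg(pm, n_hvg = config$n_hvg)
  pm <- embed_pca(pm, variance_target = config$variance_target,
                  max_components = config$max_components)
  pm <- build_knn(pm, k = config$knn_k)
  pm <- cluster_cells(pm, resolution = config$cluster_resolution,
                      seed = config$seed)
  list(pm = pm, qc_report = qc$report, removed = qc$removed)
}
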