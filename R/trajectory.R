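#' Majority-vote cluster annotation
#'
#' Assigns each cluster the most frequent label among its cells (ties break
#' lexicographically), e.g. to name clusters by planted true states or by
#' curated cell-state calls.
#'
#' @param clusters integer cluster labels per cell.
#' @param labels character labels per cell (same order).
#' @return named character vector: cluster -> majority label.
#' @export
annotate_clusters <- function(clusters, labels) {
  stopifnot(length(clusters) == length(labels))
  tab <- table(cluster = as.character(clusters), label = as.character(labels))
  out <- colnames(tab)[apply(tab, 1, which.max)]
  names(out) <- rownames(tab)
  out
}

#' Map cell states to lineage branches
#'
#' The two-branch tubal-epithelium model: secretory cells sit on the
#' secretory branch, pre-ciliated and ciliated cells on the ciliogenic
#' branch, progenitors at the root.
#'
#' @param annotation named vector cluster -> state (from
#'   [annotate_clusters()]).
#' @return named vector cluster -> branch in
#'   `{progenitor, secretory, ciliogenic}`.
#' @export
state_branch_map <- function(annotation) {
  br <- c(progenitor = "progenitor", secretory = "secretory",
          pre_ciliated = "ciliogenic", ciliated = "ciliogenic")
  unknown <- setdiff(unique(annotation), names(br))
  if (length(unknown)) {
    stopf("no branch defined for state(s): %s", paste(unknown, collapse = ", "))
  }
  setNames(br[annotation], names(annotation))
}

#' Root-anchored graph pseudotime
#'
#' The embedding is first denoised by `smooth_rounds` rounds of neighbour
#' averaging over the kNN graph (a light diffusion step standing in for the
#' heavy diffusion-based embeddings trajectory tools typically run on); a
#' trajectory graph is rebuilt on the smoothed coordinates. The root cell is
#' the medoid (minimum summed smoothed-embedding distance) of the root
#' cluster, and pseudotime is the geodesic distance from the root along the
#' distance-weighted trajectory graph. Values are raw graph distances here;
#' [assign_branches()] rescales each branch to a maximum of 1.
#'
#' @param pm a `ProcessedMatrix` with embedding, kNN graph and clusters.
#' @param root_clusters cluster label(s) forming the root (progenitor)
#'   population.
#' @param smooth_rounds diffusion-smoothing rounds before the trajectory
#'   graph is built, default 3; 0 uses the raw embedding.
#' @return list of class `Trajectory`: `root_cell`, `t_raw` (named numeric),
#'   plus fields added by later steps.
#' @export
compute_pseudotime <- function(pm, root_clusters, smooth_rounds = 3) {
  if (is.null(pm$knn) || is.null(pm$clusters)) {
    stopf("run build_knn() and cluster_cells() first")
  }
  in_root <- pm$clusters %in% root_clusters
  if (!any(in_root)) stopf("no cells in root cluster(s) %s",
                           paste(root_clusters, collapse = ", "))
  emb <- pm$embedding
  if (smooth_rounds > 0) {
    a <- igraph::as_adjacency_matrix(pm$knn$graph, sparse = TRUE)
    a <- (a > 0) * 1
    w <- a + Matrix::Diagonal(nrow(a))
    w <- Matrix::Diagonal(x = 1 / Matrix::rowSums(w)) %*% w
    for (r in seq_len(smooth_rounds)) emb <- as.matrix(w %*% emb)
    rownames(emb) <- rownames(pm$embedding)
  }
  k <- min(pm$knn$k, nrow(emb) - 1)
  nn <- knn_brute(emb, k)
  el <- cbind(rep(seq_len(nrow(emb)), each = k), as.vector(t(nn$idx)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- as.vector(t(nn$dist))
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  igraph::V(g)$name <- rownames(emb)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stopf("trajectory graph is disconnected (component sizes: %s)",
          paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  }
  emb_root <- emb[in_root, , drop = FALSE]
  d_root <- as.matrix(dist(emb_root))
  root_cell <- rownames(emb_root)[which.min(rowSums(d_root))]
  d <- igraph::distances(g, v = root_cell, weights = igraph::E(g)$weight)[1, ]
  t_raw <- d[rownames(pm$x)]
  structure(list(root_cell = root_cell, t_raw = t_raw), class = "Trajectory")
}

#' Sign pseudotime by lineage branch
#'
#' Secretory-branch cells get negative and ciliogenic-branch cells positive
#' pseudotime; progenitor cells take the sign of their nearest
#' non-progenitor graph neighbour (their magnitude stays near 0 either way).
#' Raw geodesic distances are rescaled so each branch (progenitors included)
#' spans at most magnitude 1.
#'
#' @param traj a [compute_pseudotime()] result.
#' @param pm the `ProcessedMatrix` the trajectory was computed on.
#' @param branch_map named vector cluster -> branch in
#'   `{progenitor, secretory, ciliogenic}` covering every cluster.
#' @return `traj` with `branch`, `pseudotime` (rescaled to `[0, 1]`) and
#'   `signed` (in `[-1, 1]`) added, all named by cell.
#' @export
assign_branches <- function(traj, pm, branch_map) {
  labs <- as.character(pm$clusters)
  missing_cl <- setdiff(unique(labs), names(branch_map))
  if (length(missing_cl)) {
    stopf("cluster(s) missing from branch_map: %s",
          paste(missing_cl, collapse = ", "))
  }
  branch <- unname(branch_map[labs])
  is_prog <- branch == "progenitor"
  if (any(is_prog)) {
    # nearest non-progenitor among each progenitor's ranked kNN list; the
    # embedding-nearest non-progenitor is the (rare) fallback
    idx <- pm$knn$idx
    nonprog_branch <- branch
    for (i in which(is_prog)) {
      nb <- idx[i, ]
      hit <- nb[!is_prog[nb]]
      if (length(hit)) {
        nonprog_branch[i] <- branch[hit[1]]
      } else {
        others <- which(!is_prog)
        d2 <- colSums((t(pm$embedding[others, , drop = FALSE]) -
                         pm$embedding[i, ])^2)
        nonprog_branch[i] <- branch[others[which.min(d2)]]
      }
    }
    branch_side <- nonprog_branch
  } else {
    branch_side <- branch
  }
  t_raw <- traj$t_raw
  t_scaled <- t_raw
  for (b in c("secretory", "ciliogenic")) {
    sel <- branch_side == b
    mx <- max(t_raw[sel])
    if (is.finite(mx) && mx > 0) t_scaled[sel] <- t_raw[sel] / mx
  }
  signed <- ifelse(branch_side == "secretory", -t_scaled, t_scaled)
  traj$branch <- setNames(branch, names(t_raw))
  traj$branch_side <- setNames(branch_side, names(t_raw))
  traj$pseudotime <- setNames(t_scaled, names(t_raw))
  traj$signed <- setNames(signed, names(t_raw))
  traj
}

#' Cut signed pseudotime into equal-count bins
#'
#' Cells are sorted by signed pseudotime (ties broken by cell id) and split
#' into `n_bins` contiguous groups whose sizes differ by at most one (the
#' earlier bins take the remainder). Bin 1 is the most negative
#' (secretory) end, bin `n_bins` the most positive (ciliated) end.
#'
#' @param signed named numeric vector of signed pseudotime.
#' @param n_bins number of bins, default 40.
#' @return integer bin index per cell, named, in the input cell order.
#' @export
bin_pseudotime <- function(signed, n_bins = 40) {
  n <- length(signed)
  if (n_bins > n) stopf("n_bins = %d exceeds the number of cells (%d)", n_bins, n)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  ord <- order(signed, names(signed))
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bins_sorted <- rep(seq_len(n_bins), times = sizes)
  bins <- integer(n)
  bins[ord] <- bins_sorted
  setNames(bins, names(signed))
}

#' Summarise pseudotime bins
#'
#' @param signed named signed pseudotime.
#' @param bins result of [bin_pseudotime()].
#' @param state_labels optional per-cell state labels (same order) for the
#'   majority-state column.
#' @return data frame: `bin`, `n_cells`, `mean_signed`, `majority_state`.
#' @export
bin_table <- function(signed, bins, state_labels = NULL) {
  ub <- sort(unique(bins))
  out <- data.frame(
    bin = ub,
    n_cells = as.integer(table(bins)[as.character(ub)]),
    mean_signed = as.numeric(tapply(signed, bins, mean)[as.character(ub)])
  )
  if (!is.null(state_labels)) {
    out$majority_state <- vapply(ub, function(b) {
      tt <- sort(table(state_labels[bins == b]), decreasing = TRUE)
      names(tt)[1]
    }, character(1))
  }
  out
}

#' Per-gene z-scored expression trends along bins
#'
#' Each gene is z-scored over all cells of the analysed subset (constant
#' genes give an all-zero row) and averaged within each bin.
#'
#' @param pm a `ProcessedMatrix`.
#' @param bins named bin assignment from [bin_pseudotime()] (cells must be a
#'   subset of `pm`'s cells).
#' @param genes optional gene subset.
#' @return matrix of `n_bins` rows x genes of mean z-scored expression.
#' @export
bin_expression_trends <- function(pm, bins, genes = NULL) {
  if (is.null(genes)) genes <- colnames(pm$x)
  x <- as.matrix(pm$x[names(bins), genes, drop = FALSE])
  z <- base::scale(x)
  z[!is.finite(z)] <- 0
  ub <- sort(unique(bins))
  tr <- rowsum(z, bins) / as.integer(table(bins)[as.character(ub)])
  rownames(tr) <- as.character(ub)
  tr
}

#' Rank-based gene signature score
#'
#' Per cell, all genes are ranked by decreasing expression (average ranks
#' for ties), ranks are capped at `r_max`, and the score is
#' `1 - U' / (n_s * r_max)` with `U' = sum(ranks of the signature genes) -
#' n_s (n_s + 1) / 2` — the Mann-Whitney-style statistic used for
#' single-cell signature scoring. Scores lie in `[0, 1]`; higher means the
#' signature is more highly ranked in that cell.
#'
#' @param pm a `ProcessedMatrix`.
#' @param gene_set character vector of signature genes; unknown genes are
#'   dropped with a warning.
#' @param r_max rank cap, default 1500.
#' @return named numeric score per cell.
#' @export
score_signature <- function(pm, gene_set, r_max = 1500) {
  if (!length(gene_set)) stopf("empty gene set")
  known <- gene_set %in% colnames(pm$x)
  if (any(!known)) {
    warnf("dropping %d unknown signature gene(s): %s", sum(!known),
          paste(head(gene_set[!known], 5), collapse = ", "))
  }
  gene_set <- unique(gene_set[known])
  if (!length(gene_set)) stopf("no signature genes present in the matrix")
  ns <- length(gene_set)
  if (ns >= r_max) stopf("signature size (%d) must be below the rank cap (%d)", ns, r_max)
  x <- as.matrix(pm$x)
  sig_idx <- match(gene_set, colnames(x))
  scores <- apply(x, 1, function(row) {
    rk <- rank(-row, ties.method = "average")
    rk <- pmin(rk, r_max)
    u <- sum(rk[sig_idx]) - ns * (ns + 1) / 2
    1 - u / (ns * r_max)
  })
  setNames(scores, rownames(x))
}

#' Full trajectory analysis of one species
#'
#' Pseudotime from the progenitor root, branch signing, equal-count binning
#' and z-scored bin trends in one call.
#'
#' @param pm a processed, clustered `ProcessedMatrix`.
#' @param annotation named vector cluster -> state; must use the states
#'   `progenitor`, `secretory`, `pre_ciliated`, `ciliated`.
#' @param n_bins number of pseudotime bins, default 40.
#' @param state_labels optional per-cell labels for the bin majority-state
#'   column; defaults to the cluster annotation applied to each cell.
#' @return a `Trajectory` list with `root_cell`, `pseudotime`, `branch`,
#'   `signed`, `bins`, `bin_table`, `trends`.
#' @export
run_trajectory <- function(pm, annotation, n_bins = 40, state_labels = NULL) {
  branch_map <- state_branch_map(annotation)
  root_clusters <- names(annotation)[annotation == "progenitor"]
  if (!length(root_clusters)) stopf("no cluster annotated as progenitor")
  traj <- compute_pseudotime(pm, root_clusters)
  traj <- assign_branches(traj, pm, branch_map)
  traj$bins <- bin_pseudotime(traj$signed, n_bins)
  if (is.null(state_labels)) {
    state_labels <- unname(annotation[as.character(pm$clusters)])
  }
  traj$state_labels <- setNames(state_labels, names(traj$signed))
  traj$bin_table <- bin_table(traj$signed, traj$bins, state_labels)
  traj$trends <- bin_expression_trends(pm, traj$bins)
  traj
}
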