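#' Joint cross-species embedding and neighbour search
#'
#' A single-round, homology-seeded alignment: species-B expression is
#' translated into species-A gene space through the bitscore-weighted
#' translation map, the shared (ortholog-covered) dimensions are z-scored
#' within each species, and each cell's `k_cross` nearest cross-species
#' neighbours are found by exact Euclidean search in that shared space.
#' This deliberately replaces iterative manifold/homology refinement with
#' one deterministic round; the outputs keep the same semantics (cluster
#' alignment scores, cross-species gene-pair correlations).
#'
#' @param pm_a,pm_b `ProcessedMatrix` objects of the two species (with kNN
#'   graphs built, used for denoising the joint coordinates and later for
#'   smoothing).
#' @param translation result of [build_gene_translation()] whose `ba` matrix
#'   maps species-B genes onto species-A genes.
#' @param k_cross cross-species neighbours per cell, default 20.
#' @param n_joint_pcs dimensionality of the joint principal-component space
#'   the cross search runs in, default 50.
#' @return an object of class `JointMap`: list with `ab` / `ba` cross
#'   neighbour lists (`idx`, `dist` matrices), the joint-PC coordinates
#'   `z_a` / `z_b`, `shared_genes`, `translation`, and the two
#'   `ProcessedMatrix` inputs.
#' @export
joint_embed <- function(pm_a, pm_b, translation, k_cross = 20,
                        n_joint_pcs = 50) {
  tr <- translation$ba[colnames(pm_b$x), colnames(pm_a$x), drop = FALSE]
  shared <- colnames(pm_a$x)[Matrix::colSums(tr) > 0]
  if (!length(shared)) stopf("empty translation: no ortholog-covered genes")
  x_a <- as.matrix(pm_a$x[, shared, drop = FALSE])
  x_bt <- as.matrix(pm_b$x %*% tr[, shared, drop = FALSE])
  zs <- function(m) {
    m <- base::scale(m)
    m[!is.finite(m)] <- 0
    m
  }
  z_a <- zs(x_a); z_b <- zs(x_bt)
  smooth_coords <- function(pm, m) {
    a <- igraph::as_adjacency_matrix(pm$knn$graph, sparse = TRUE)
    a <- (a > 0) * 1
    w <- a + Matrix::Diagonal(nrow(a))
    as.matrix(Matrix::Diagonal(x = 1 / Matrix::rowSums(w)) %*% w %*% m)
  }
  # denoise the shared space: joint PCA over both species' cells, then one
  # round of within-species neighbour smoothing of the joint coordinates —
  # cross-species distances in the raw z-space are noise-dominated
  embed_once <- function(za, zb) {
    rank <- min(n_joint_pcs, ncol(za), nrow(za) + nrow(zb) - 1)
    pc <- prcomp(rbind(za, zb), center = TRUE, scale. = FALSE, rank. = rank)
    j_a <- smooth_coords(pm_a, pc$x[seq_len(nrow(za)), , drop = FALSE])
    j_b <- smooth_coords(pm_b, pc$x[nrow(za) + seq_len(nrow(zb)), , drop = FALSE])
    rownames(j_a) <- rownames(pm_a$x); rownames(j_b) <- rownames(pm_b$x)
    list(a = j_a, b = j_b,
         ab = knn_brute(j_b, k_cross, query = j_a, self = FALSE),
         ba = knn_brute(j_a, k_cross, query = j_b, self = FALSE))
  }
  em <- embed_once(z_a, z_b)
  # one concordance-refinement round: shared dimensions whose expression
  # disagrees across the initial map (e.g. divergent orthologs, whose two
  # species run different programs) are down-weighted before the final
  # embedding, mirroring the homology reweighting of iterative aligners —
  # without it such dimensions displace the two species' branch tips apart
  p_ab <- cross_operator(em$ab$idx, nrow(z_b))
  p_ba <- cross_operator(em$ba$idx, nrow(z_a))
  d_ab <- suppressWarnings(
    vapply(seq_len(ncol(z_a)),
           function(g) cor(z_a[, g], (p_ab %*% z_b[, g])[, 1]), numeric(1)))
  d_ba <- suppressWarnings(
    vapply(seq_len(ncol(z_a)),
           function(g) cor(z_b[, g], (p_ba %*% z_a[, g])[, 1]), numeric(1)))
  w_dim <- pmax((d_ab + d_ba) / 2, 0)
  w_dim[is.na(w_dim)] <- 0
  em <- embed_once(sweep(z_a, 2, w_dim, "*"), sweep(z_b, 2, w_dim, "*"))
  structure(list(ab = em$ab, ba = em$ba, z_a = em$a, z_b = em$b,
                 shared_genes = shared, dim_weights = setNames(w_dim, shared),
                 translation = translation,
                 k_cross = k_cross, pm_a = pm_a, pm_b = pm_b),
            class = "JointMap")
}

#' @export
print.JointMap <- function(x, ...) {
  cat(sprintf("JointMap: %d + %d cells, %d shared dimensions, k_cross = %d\n",
              nrow(x$z_a), nrow(x$z_b), length(x$shared_genes), x$k_cross))
  invisible(x)
}

#' Cluster-pair alignment scores
#'
#' For clusters i (species A) and j (species B),
#' `score(i, j) = 1/2 * [ mean over cells of i of the fraction of their
#' cross-species neighbours lying in j + the symmetric term ]`. Scores lie
#' in `[0, 1]`; 1 means fully reciprocal neighbourhoods. The best-match
#' pairing (argmax per cluster, Sankey-style) is also returned.
#'
#' @param jm a [joint_embed()] result.
#' @param labels_a,labels_b per-cell cluster labels (named or in cell order).
#' @return list with `scores` (matrix, A clusters x B clusters), `pairs_a`
#'   (data frame: each A cluster's best B partner and score), `pairs_b`.
#' @export
alignment_scores <- function(jm, labels_a, labels_b) {
  n_a <- nrow(jm$z_a); n_b <- nrow(jm$z_b)
  if (length(labels_a) != n_a || length(labels_b) != n_b) {
    stopf("label vectors (%d, %d) do not match cell counts (%d, %d)",
          length(labels_a), length(labels_b), n_a, n_b)
  }
  la <- as.character(labels_a); lb <- as.character(labels_b)
  ua <- sort(unique(la)); ub <- sort(unique(lb))
  # fraction of each cell's cross neighbours per partner cluster
  frac_by <- function(idx, partner_labels, u_partner) {
    k <- ncol(idx)
    m <- matrix(0, nrow(idx), length(u_partner),
                dimnames = list(NULL, u_partner))
    pl <- matrix(partner_labels[idx], nrow = nrow(idx))
    for (j in seq_along(u_partner)) {
      m[, j] <- rowSums(pl == u_partner[j]) / k
    }
    m
  }
  fa <- frac_by(jm$ab$idx, lb, ub)   # A cells -> fraction in each B cluster
  fb <- frac_by(jm$ba$idx, la, ua)   # B cells -> fraction in each A cluster
  s_ab <- rowsum(fa, la) / as.vector(table(la)[ua])
  s_ba <- rowsum(fb, lb) / as.vector(table(lb)[ub])
  scores <- (s_ab[ua, ub, drop = FALSE] + t(s_ba[ub, ua, drop = FALSE])) / 2
  pairs_a <- data.frame(cluster_a = ua,
                        best_b = ub[apply(scores, 1, which.max)],
                        score = apply(scores, 1, max),
                        stringsAsFactors = FALSE)
  pairs_b <- data.frame(cluster_b = ub,
                        best_a = ua[apply(scores, 2, which.max)],
                        score = apply(scores, 2, max),
                        stringsAsFactors = FALSE)
  list(scores = scores, pairs_a = pairs_a, pairs_b = pairs_b)
}

#' Neighbourhood smoothing of expression
#'
#' Each cell's value is replaced by the unweighted mean over the cell itself
#' and its graph neighbours: `(D + I)^-1 (A + I) x` for adjacency `A` and
#' degree matrix `D`. Optionally only each cell's `k` nearest neighbours are
#' used (a directed sub-graph of the kNN graph), which narrows the smoothing
#' bandwidth and preserves finer expression structure.
#'
#' @param pm a `ProcessedMatrix` with `knn` built.
#' @param genes optional gene subset (ids or indices); default all.
#' @param k optional neighbour count below the graph's `k`; `NULL` uses the
#'   full symmetrised graph.
#' @return dense matrix of smoothed expression (cells x genes).
#' @export
smooth_expression <- function(pm, genes = NULL, k = NULL) {
  if (is.null(pm$knn)) stopf("run build_knn() before smoothing")
  if (is.null(genes)) genes <- colnames(pm$x)
  if (is.null(k) || k >= pm$knn$k) {
    a <- igraph::as_adjacency_matrix(pm$knn$graph, sparse = TRUE)
    a <- (a > 0) * 1
  } else {
    idx <- pm$knn$idx[, seq_len(k), drop = FALSE]
    a <- Matrix::sparseMatrix(i = rep(seq_len(nrow(idx)), k),
                              j = as.vector(idx), x = 1,
                              dims = c(nrow(idx), nrow(idx)))
  }
  w <- a + Matrix::Diagonal(nrow(a))
  w <- Matrix::Diagonal(x = 1 / Matrix::rowSums(w)) %*% w
  out <- as.matrix(w %*% pm$x[, genes, drop = FALSE])
  dimnames(out) <- list(rownames(pm$x), colnames(pm$x[, genes, drop = FALSE]))
  out
}

# row-stochastic cross-neighbour averaging matrix (n_query x n_partner)
cross_operator <- function(idx, n_partner) {
  k <- ncol(idx)
  Matrix::sparseMatrix(i = rep(seq_len(nrow(idx)), k), j = as.vector(idx),
                       x = 1 / k, dims = c(nrow(idx), n_partner))
}

# symmetric cross-species correlation matrix for gene sets; direction A uses
# smoothed gene_a expression on A cells vs gene_b imputed from A->B cross
# neighbours, direction B mirrors it; the mean of both is returned
pair_correlation_matrix <- function(jm, genes_a, genes_b) {
  k_sm <- min(20L, jm$pm_a$knn$k, jm$pm_b$knn$k)
  s_a <- smooth_expression(jm$pm_a, genes_a, k = k_sm)
  s_b <- smooth_expression(jm$pm_b, genes_b, k = k_sm)
  p_ab <- cross_operator(jm$ab$idx, nrow(jm$z_b))
  p_ba <- cross_operator(jm$ba$idx, nrow(jm$z_a))
  # imputation averages the partner's smoothed expression over the cross
  # neighbours, so both sides of the correlation are denoised comparably
  imp_b_on_a <- as.matrix(p_ab %*% s_b)
  imp_a_on_b <- as.matrix(p_ba %*% s_a)
  c_a <- suppressWarnings(cor(s_a, imp_b_on_a))
  c_b <- suppressWarnings(cor(imp_a_on_b, s_b))
  out <- (c_a + c_b) / 2
  dimnames(out) <- list(genes_a, genes_b)
  out
}

#' Cross-species gene-pair correlation
#'
#' Pearson correlation between smoothed `gene_a` expression on species-A
#' cells and smoothed `gene_b` expression imputed onto those cells as the
#' unweighted mean over each cell's cross-species neighbours; the symmetric
#' value (the
#' average of both directions) is reported. A constant profile on either
#' side makes the correlation undefined: `NA` is returned with a warning,
#' never a silent 0.
#'
#' @param jm a [joint_embed()] result.
#' @param gene_a,gene_b gene ids in species A / B.
#' @return numeric in `[-1, 1]`, or `NA` if undefined.
#' @export
gene_pair_correlation <- function(jm, gene_a, gene_b) {
  if (!gene_a %in% colnames(jm$pm_a$x)) stopf("unknown species-A gene '%s'", gene_a)
  if (!gene_b %in% colnames(jm$pm_b$x)) stopf("unknown species-B gene '%s'", gene_b)
  v <- pair_correlation_matrix(jm, gene_a, gene_b)[1, 1]
  if (is.na(v)) {
    warnf("correlation of (%s, %s) is undefined (constant profile)",
          gene_a, gene_b)
  }
  unname(v)
}

# top-variance genes of a ProcessedMatrix (by log-normalised variance)
top_variable_genes <- function(pm, n) {
  st <- col_stats(pm$x)
  ord <- order(-st$var, colnames(pm$x))
  colnames(pm$x)[ord[seq_len(min(n, ncol(pm$x)))]]
}

#' Find aligned cross-species gene pairs
#'
#' Scores a candidate pair universe — all homology pairs plus the cross
#' product of the two species' top-variable gene sets — by symmetric
#' cross-species correlation, and keeps pairs with correlation strictly
#' above `min_corr`, each annotated with its bitscore and inverse bitscore
#' (`Inf` when no homology record exists).
#'
#' @param jm a [joint_embed()] result.
#' @param homology a `HomologyTable`.
#' @param min_corr correlation floor (strict), default 0.2.
#' @param top_var per-species size of the top-variable gene set, default 250.
#' @return a `GenePairScore` data frame: `gene_a`, `gene_b`, `correlation`,
#'   `bitscore` (`NA` if absent), `inverse_bitscore`, sorted by decreasing
#'   correlation.
#' @export
find_gene_pairs <- function(jm, homology, min_corr = 0.2, top_var = 250) {
  ga <- colnames(jm$pm_a$x); gb <- colnames(jm$pm_b$x)
  hom <- homology[homology$gene_a %in% ga & homology$gene_b %in% gb, , drop = FALSE]
  tv_a <- top_variable_genes(jm$pm_a, top_var)
  tv_b <- top_variable_genes(jm$pm_b, top_var)
  cand <- unique(rbind(
    data.frame(gene_a = hom$gene_a, gene_b = hom$gene_b, stringsAsFactors = FALSE),
    expand.grid(gene_a = tv_a, gene_b = tv_b, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  ))
  ua <- unique(cand$gene_a); ub <- unique(cand$gene_b)
  cm <- pair_correlation_matrix(jm, ua, ub)
  corr <- cm[cbind(match(cand$gene_a, ua), match(cand$gene_b, ub))]
  n_na <- sum(is.na(corr))
  if (n_na) am_log("warn", "%d candidate pair(s) had undefined correlation", n_na)
  keep <- !is.na(corr) & corr > min_corr
  out <- data.frame(gene_a = cand$gene_a[keep], gene_b = cand$gene_b[keep],
                    correlation = corr[keep], stringsAsFactors = FALSE)
  inv <- inverse_blast(out$gene_a, out$gene_b, homology)
  out$bitscore <- ifelse(is.finite(inv), 1 / inv, NA_real_)
  out$inverse_bitscore <- inv
  out <- out[order(-out$correlation, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  class(out) <- c("GenePairScore", "data.frame")
  out
}
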