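#' Top distinguishing markers per cell state
#'
#' From a one-vs-rest `MarkerTable`, selects for each state the `n_top`
#' genes with positive fold change, ordered by adjusted p-value (ascending)
#' then log fold change (descending), ties by gene id. Cluster labels are
#' mapped to states through `annotation` (several clusters may share a
#' state; each gene then keeps its best record). Lists are prefix-stable:
#' the top-5 of a state is a prefix of its top-10.
#'
#' @param marker_table result of [rank_markers_wilcoxon()].
#' @param n_top markers per state, default 40.
#' @param annotation optional named vector cluster -> state; if `NULL` the
#'   cluster labels themselves are the states.
#' @return named list: state -> character vector of gene ids.
#' @export
top_state_markers <- function(marker_table, n_top = 40, annotation = NULL) {
  mt <- as.data.frame(marker_table)
  mt$state <- if (is.null(annotation)) as.character(mt$cluster) else {
    unname(annotation[as.character(mt$cluster)])
  }
  out <- list()
  for (s in sort(unique(mt$state))) {
    rec <- mt[mt$state == s & mt$log_fold_change > 0, , drop = FALSE]
    rec <- rec[order(rec$adjusted_p, -rec$log_fold_change, rec$gene), , drop = FALSE]
    rec <- rec[!duplicated(rec$gene), , drop = FALSE]
    if (nrow(rec) < n_top) {
      warnf("state '%s' has only %d qualifying markers (%d requested)",
            s, nrow(rec), n_top)
    }
    out[[s]] <- head(rec$gene, n_top)
  }
  out
}

# highest-bitscore partner of each gene, from the given side of the table
best_ortholog <- function(genes, homology, from = c("a", "b")) {
  from <- match.arg(from)
  src <- if (from == "a") homology$gene_a else homology$gene_b
  dst <- if (from == "a") homology$gene_b else homology$gene_a
  vapply(genes, function(g) {
    hit <- which(src == g)
    if (!length(hit)) return(NA_character_)
    dst[hit[which.max(homology$bitscore[hit])]]
  }, character(1))
}

#' Classify markers as conserved or species-specific
#'
#' Every state marker is paired with its highest-bitscore ortholog and the
#' pair's symmetric cross-species correlation is computed on the joint map.
#' Markers whose ortholog pair correlates strictly above `threshold` are
#' conserved (reported with the correlation, sorted descending); markers
#' with no ortholog, or whose pair correlation is at or below the
#' threshold, are species-specific (sorted ascending, missing correlations
#' first). The three per-state lists are disjoint on genes: a gene entering
#' a conserved pair is dropped from the specific lists.
#'
#' @param state_markers_a,state_markers_b per-state gene lists from
#'   [top_state_markers()] for species A / B.
#' @param homology a `HomologyTable`.
#' @param jm a [joint_embed()] result.
#' @param threshold conservation correlation floor (strict), default 0.2.
#' @return a `ConservationReference` data frame: `state`, `class` in
#'   `{conserved, a_specific, b_specific}`, `gene_a`, `gene_b`,
#'   `correlation` (`NA` when no ortholog exists).
#' @export
classify_conservation <- function(state_markers_a, state_markers_b, homology,
                                  jm, threshold = 0.2) {
  states <- sort(union(names(state_markers_a), names(state_markers_b)))
  rows <- list()
  for (s in states) {
    ga <- state_markers_a[[s]]
    gb <- state_markers_b[[s]]
    part_a <- best_ortholog(ga, homology, "a")
    part_b <- best_ortholog(gb, homology, "b")
    pairs <- unique(rbind(
      data.frame(gene_a = ga, gene_b = unname(part_a), stringsAsFactors = FALSE),
      data.frame(gene_a = unname(part_b), gene_b = gb, stringsAsFactors = FALSE)
    ))
    pairs <- pairs[!is.na(pairs$gene_a) & !is.na(pairs$gene_b), , drop = FALSE]
    pairs <- pairs[pairs$gene_a %in% colnames(jm$pm_a$x) &
                     pairs$gene_b %in% colnames(jm$pm_b$x), , drop = FALSE]
    corr <- if (nrow(pairs)) {
      cmat <- pair_correlation_matrix(jm, unique(pairs$gene_a), unique(pairs$gene_b))
      cmat[cbind(match(pairs$gene_a, rownames(cmat)),
                 match(pairs$gene_b, colnames(cmat)))]
    } else numeric(0)
    cons <- pairs[!is.na(corr) & corr > threshold, , drop = FALSE]
    cons$correlation <- corr[!is.na(corr) & corr > threshold]
    cons <- cons[order(-cons$correlation), , drop = FALSE]
    corr_of_a <- setNames(corr, pairs$gene_a)[ga]
    corr_of_b <- setNames(corr, pairs$gene_b)[gb]
    a_spec <- setdiff(ga[is.na(corr_of_a) | corr_of_a <= threshold],
                      c(cons$gene_a))
    b_spec <- setdiff(gb[is.na(corr_of_b) | corr_of_b <= threshold],
                      c(cons$gene_b))
    a_corr <- corr_of_a[match(a_spec, ga)]
    b_corr <- corr_of_b[match(b_spec, gb)]
    a_ord <- order(!is.na(a_corr), a_corr, a_spec)
    b_ord <- order(!is.na(b_corr), b_corr, b_spec)
    add <- function(state, class, gene_a, gene_b, correlation) {
      if (!length(gene_a) && !length(gene_b)) return(NULL)
      data.frame(state = state, class = class,
                 gene_a = gene_a, gene_b = gene_b,
                 correlation = correlation, stringsAsFactors = FALSE)
    }
    rows[[s]] <- rbind(
      if (nrow(cons)) add(s, "conserved", cons$gene_a, cons$gene_b, cons$correlation),
      add(s, "a_specific", a_spec[a_ord], rep(NA_character_, length(a_spec)),
          unname(a_corr[a_ord])),
      add(s, "b_specific", rep(NA_character_, length(b_spec)), b_spec[b_ord],
          unname(b_corr[b_ord]))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ConservationReference", "data.frame")
  out
}

#' Functional-category scores per cell state
#'
#' For a user-supplied two-column gene-to-category map, each gene's mean
#' log-normalised expression per state is z-scored across states, and the
#' category score is the mean of these z-scores over the category's genes.
#' Categories with no expressed gene are dropped with a warning.
#'
#' @param pm a `ProcessedMatrix`.
#' @param state_labels per-cell state labels (in cell order, or named).
#' @param gene_to_category data frame with columns `gene`, `category`.
#' @return matrix of scores, states x categories.
#' @export
category_scores <- function(pm, state_labels, gene_to_category) {
  stopifnot(all(c("gene", "category") %in% names(gene_to_category)))
  labs <- as.character(state_labels)
  genes <- intersect(unique(gene_to_category$gene), colnames(pm$x))
  if (!length(genes)) stopf("no category gene present in the matrix")
  x <- as.matrix(pm$x[, genes, drop = FALSE])
  sm <- rowsum(x, labs) / as.vector(table(labs)[sort(unique(labs))])
  z <- base::scale(sm)
  z[!is.finite(z)] <- 0
  cats <- sort(unique(gene_to_category$category))
  out <- matrix(NA_real_, nrow(sm), 0, dimnames = list(rownames(sm), NULL))
  kept <- character(0)
  for (ct in cats) {
    g <- intersect(gene_to_category$gene[gene_to_category$category == ct], genes)
    if (!length(g)) {
      warnf("category '%s' has no expressed gene; dropped", ct)
      next
    }
    out <- cbind(out, rowMeans(z[, g, drop = FALSE]))
    kept <- c(kept, ct)
  }
  colnames(out) <- kept
  out
}
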