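#' Filter gene pairs to analog surface-marker candidates
#'
#' Keeps the pairs whose species-B gene is an annotated surface marker,
#' whose symmetric correlation is strictly above `analog_corr_min` and
#' whose inverse bitscore is strictly above `inv_bitscore_min` (pairs with
#' no homology record carry `Inf` and always pass that filter). The result
#' is a subset of the input; the filter is idempotent and anti-monotone in
#' its thresholds.
#'
#' @param pairs a `GenePairScore` data frame from [find_gene_pairs()].
#' @param surface_set character vector of species-B surface-marker genes; an
#'   empty set yields an empty result with a warning.
#' @param config a [pipeline_config()] supplying `analog_corr_min` and
#'   `inv_bitscore_min`.
#' @return an `AnalogCandidate` data frame: `gene_a`, `gene_b`,
#'   `correlation`, `inverse_bitscore`, `surface_flag`.
#' @export
filter_analog_candidates <- function(pairs, surface_set,
                                     config = pipeline_config()) {
  if (!length(surface_set)) {
    warnf("empty surface-marker set: no analog candidates can be retained")
  }
  keep <- pairs$gene_b %in% surface_set &
    pairs$correlation > config$analog_corr_min &
    pairs$inverse_bitscore > config$inv_bitscore_min
  out <- pairs[keep, c("gene_a", "gene_b", "correlation", "inverse_bitscore"),
               drop = FALSE]
  out$surface_flag <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("AnalogCandidate", "data.frame")
  out
}

#' Progenitor-lineage specificity fold change
#'
#' For each gene, the ratio of mean log-normalised expression over cells in
#' progenitor-majority pseudotime bins to the mean over cells of all other
#' bins, with a small epsilon guarding empty means:
#' `(mean_prog + eps) / (mean_other + eps)`.
#'
#' @param pm a `ProcessedMatrix` (log-normalised, not z-scored).
#' @param bins named bin assignment from [bin_pseudotime()].
#' @param bin_states data frame with columns `bin` and `majority_state`
#'   (e.g. [bin_table()] output), or a vector of majority states per bin.
#' @param genes optional gene subset.
#' @param eps pseudocount, default 1e-4.
#' @param progenitor_label label marking progenitor bins, default
#'   `"progenitor"`.
#' @return named numeric fold change per gene.
#' @export
progenitor_specificity <- function(pm, bins, bin_states, genes = NULL,
                                   eps = 1e-4, progenitor_label = "progenitor") {
  if (is.data.frame(bin_states)) {
    maj <- setNames(as.character(bin_states$majority_state),
                    as.character(bin_states$bin))
  } else {
    maj <- setNames(as.character(bin_states), names(bin_states))
  }
  prog_bins <- names(maj)[maj == progenitor_label]
  if (!length(prog_bins)) stopf("no progenitor-majority bin found")
  if (is.null(genes)) genes <- colnames(pm$x)
  in_prog <- as.character(bins) %in% prog_bins
  x <- pm$x[names(bins), genes, drop = FALSE]
  m_prog <- Matrix::colSums(x[in_prog, , drop = FALSE]) / sum(in_prog)
  m_other <- Matrix::colSums(x[!in_prog, , drop = FALSE]) / sum(!in_prog)
  setNames((m_prog + eps) / (m_other + eps), genes)
}

#' Rank analog candidates by progenitor specificity
#'
#' Ranked terms are species-B surface genes: each `gene_b` first keeps its
#' best pair (highest correlation, ties by `gene_a` id), then terms are
#' sorted by the gene's progenitor fold change (descending), ties broken by
#' correlation (descending) then `gene_b` id; the first `top_k` are
#' returned with a gap-free `rank` and their `progenitor_fold_change`.
#'
#' @param candidates an `AnalogCandidate` data frame.
#' @param specificity named fold-change vector from
#'   [progenitor_specificity()], covering every candidate's `gene_b`.
#' @param top_k number of candidates to emit, default 10.
#' @return the ranked `AnalogCandidate` data frame.
#' @export
rank_candidates <- function(candidates, specificity, top_k = 10) {
  fc <- unname(specificity[candidates$gene_b])
  if (anyNA(fc)) {
    stopf("specificity missing for gene(s): %s",
          paste(head(candidates$gene_b[is.na(fc)], 5), collapse = ", "))
  }
  out <- candidates
  out$progenitor_fold_change <- fc
  best <- order(-out$correlation, out$gene_a)
  out <- out[best, , drop = FALSE]
  out <- out[!duplicated(out$gene_b), , drop = FALSE]
  ord <- order(-out$progenitor_fold_change, -out$correlation, out$gene_b)
  out <- out[head(ord, top_k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("AnalogCandidate", "data.frame")
  out
}
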