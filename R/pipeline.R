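#' Read a dataset directory
#'
#' Loads the two species' MTX triplets, the homology table, the surface
#' list, signatures and gene-category map written by [write_dataset()] (or
#' assembled by hand in the same layout).
#'
#' @param dir dataset directory.
#' @param mito_prefixes mitochondrial gene-name prefixes.
#' @return list with `A`, `B` (`CountMatrix`), `homology`, `surface`,
#'   `signatures`, `categories`, and `truth` when `truth.json` is present.
#' @export
read_dataset <- function(dir, mito_prefixes = c("mt-", "MT-")) {
  out <- list(
    A = read_counts_mtx(file.path(dir, "species_a"), mito_prefixes),
    B = read_counts_mtx(file.path(dir, "species_b"), mito_prefixes),
    homology = read_blast6(file.path(dir, "homology.tsv"))
  )
  sp <- file.path(dir, "surface_markers.txt")
  out$surface <- if (file.exists(sp)) readLines(sp) else character(0)
  sg <- file.path(dir, "signatures.tsv")
  if (file.exists(sg)) out$signatures <- read.delim(sg, stringsAsFactors = FALSE)
  ct <- file.path(dir, "gene_categories.tsv")
  if (file.exists(ct)) out$categories <- read.delim(ct, stringsAsFactors = FALSE)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- read_truth(tj)
  out
}

#' Run the full cross-species analysis
#'
#' End-to-end orchestration: per-species QC, normalisation, feature
#' selection, embedding, neighbour graph and clustering; cluster annotation
#' (by majority over `true_state` metadata when present, otherwise user
#' supplied); homology-weighted joint embedding with cluster alignment
#' scores; gene-pair correlation screening; per-species marker detection and
#' the conservation reference; signed pseudotime with binning and trends per
#' species; and the analog candidate filter-and-rank on the species-B
#' surface set.
#'
#' @param data a [read_dataset()]-shaped list (also accepts the in-memory
#'   output of [simulate_counts()] plus homology/surface fields).
#' @param config_a,config_b per-species configurations; defaults are the
#'   mouse-style (30% mito) and human-style (20% mito) presets.
#' @param annotations optional list with named vectors `A`, `B` mapping
#'   clusters to states; by default clusters are annotated by majority vote
#'   over the `true_state` cell metadata.
#' @param state_source labels used for bin majority states: `"cluster"`
#'   (cluster annotation, default) or `"truth"` (`true_state` metadata).
#' @return a list of class `CrossSpeciesAnalysis` with elements `proc_a`,
#'   `proc_b`, `annotation_a`, `annotation_b`, `jm`, `alignment`,
#'   `alignment_states`, `pairs`, `markers_a`, `markers_b`,
#'   `state_markers_a`, `state_markers_b`, `conservation`, `traj_a`,
#'   `traj_b`, `specificity_b`, `analog_candidates`, `qc_a`, `qc_b`.
#' @export
analyze_dataset <- function(data,
                            config_a = qc_preset("mouse"),
                            config_b = qc_preset("human"),
                            annotations = NULL,
                            state_source = c("cluster", "truth")) {
  state_source <- match.arg(state_source)
  am_log("info", "processing species A (%d cells)", nrow(data$A$counts))
  res_a <- process_species(data$A, config_a)
  am_log("info", "processing species B (%d cells)", nrow(data$B$counts))
  res_b <- process_species(data$B, config_b)
  pm_a <- res_a$pm; pm_b <- res_b$pm

  get_annot <- function(pm, given) {
    if (!is.null(given)) return(given)
    if (!"true_state" %in% names(pm$cell_meta)) {
      stopf("no annotation supplied and no true_state metadata available")
    }
    annotate_clusters(pm$clusters, pm$cell_meta$true_state)
  }
  ann_a <- get_annot(pm_a, annotations$A)
  ann_b <- get_annot(pm_b, annotations$B)

  translation <- build_gene_translation(data$homology,
                                        colnames(pm_a$x), colnames(pm_b$x))
  jm <- joint_embed(pm_a, pm_b, translation, k_cross = config_a$k_cross)
  align <- alignment_scores(jm, pm_a$clusters, pm_b$clusters)
  align_states <- alignment_scores(jm,
                                   unname(ann_a[as.character(pm_a$clusters)]),
                                   unname(ann_b[as.character(pm_b$clusters)]))
  pairs <- find_gene_pairs(jm, data$homology,
                           min_corr = config_a$conservation_corr_min,
                           top_var = config_a$top_var_genes)

  mk_a <- rank_markers_wilcoxon(pm_a)
  mk_b <- rank_markers_wilcoxon(pm_b)
  sm_a <- top_state_markers(mk_a, n_top = config_a$n_top_markers, annotation = ann_a)
  sm_b <- top_state_markers(mk_b, n_top = config_b$n_top_markers, annotation = ann_b)
  consref <- classify_conservation(sm_a, sm_b, data$homology, jm,
                                   threshold = config_a$conservation_corr_min)

  states_of <- function(pm, ann) {
    if (state_source == "truth") pm$cell_meta$true_state
    else unname(ann[as.character(pm$clusters)])
  }
  traj_a <- run_trajectory(pm_a, ann_a, n_bins = config_a$n_bins,
                           state_labels = states_of(pm_a, ann_a))
  traj_b <- run_trajectory(pm_b, ann_b, n_bins = config_b$n_bins,
                           state_labels = states_of(pm_b, ann_b))

  cand <- filter_analog_candidates(pairs, data$surface, config_a)
  spec_b <- progenitor_specificity(pm_b, traj_b$bins, traj_b$bin_table)
  ranked <- rank_candidates(cand, spec_b, top_k = config_a$top_k)

  structure(list(
    proc_a = pm_a, proc_b = pm_b,
    qc_a = res_a$qc_report, qc_b = res_b$qc_report,
    removed_a = res_a$removed, removed_b = res_b$removed,
    annotation_a = ann_a, annotation_b = ann_b,
    jm = jm, alignment = align, alignment_states = align_states,
    pairs = pairs,
    markers_a = mk_a, markers_b = mk_b,
    state_markers_a = sm_a, state_markers_b = sm_b,
    conservation = consref,
    traj_a = traj_a, traj_b = traj_b,
    specificity_b = spec_b,
    analog_candidates = ranked,
    config_a = config_a, config_b = config_b
  ), class = "CrossSpeciesAnalysis")
}

#' @export
print.CrossSpeciesAnalysis <- function(x, ...) {
  cat("CrossSpeciesAnalysis\n")
  cat(sprintf("  species A: %d cells, %d clusters\n",
              nrow(x$proc_a$x), length(unique(x$proc_a$clusters))))
  cat(sprintf("  species B: %d cells, %d clusters\n",
              nrow(x$proc_b$x), length(unique(x$proc_b$clusters))))
  cat(sprintf("  aligned gene pairs (corr > threshold): %d\n", nrow(x$pairs)))
  cat(sprintf("  analog candidates emitted: %d\n", nrow(x$analog_candidates)))
  invisible(x)
}

#' Evaluate an analysis against planted truth
#'
#' Computes the recovery metrics the synthetic design supports: clustering
#' agreement with true states (adjusted Rand index), per-branch Spearman
#' correlation of pseudotime with latent time, branch-sign accuracy,
#' conservation-classification precision/recall per class, analog recall in
#' the ranked top-k, and whether any ortholog record leaks through the
#' inverse-bitscore filter.
#'
#' @param res a [analyze_dataset()] result.
#' @param truth the matching `SyntheticTruth`.
#' @return named list of metrics.
#' @export
evaluate_against_truth <- function(res, truth) {
  pm_b <- res$proc_b
  # clustering ARI vs true states (species A, post-QC cells)
  ari_a <- adjusted_rand(res$proc_a$clusters, res$proc_a$cell_meta$true_state)
  ari_b <- adjusted_rand(pm_b$clusters, pm_b$cell_meta$true_state)

  spearman_branch <- function(traj, pm) {
    keep <- pm$cell_meta$true_state %in% .states
    out <- c(secretory = NA_real_, ciliogenic = NA_real_)
    for (b in names(out)) {
      sel <- keep & pm$cell_meta$true_branch == b &
        traj$branch_side == b
      if (sum(sel) > 2) {
        out[b] <- suppressWarnings(
          cor(traj$pseudotime[sel], pm$cell_meta$true_time[sel],
              method = "spearman"))
      }
    }
    out
  }
  sp_a <- spearman_branch(res$traj_a, res$proc_a)
  sp_b <- spearman_branch(res$traj_b, pm_b)

  sign_acc <- function(traj, pm) {
    sel <- pm$cell_meta$true_state %in% c("secretory", "pre_ciliated", "ciliated")
    mean(traj$branch_side[sel] == pm$cell_meta$true_branch[sel])
  }

  # conservation classification, judged on planted marker genes only (other
  # genes in the reference, e.g. gradient orthologs, are genuinely conserved
  # and are neither hits nor errors)
  cons <- res$conservation
  planted <- list(
    cons_a = unlist(lapply(truth$markers, function(m) m$conserved$gene_a)),
    cons_b = unlist(lapply(truth$markers, function(m) m$conserved$gene_b)),
    spec_a = unlist(lapply(truth$markers, function(m) m$a_specific)),
    spec_b = unlist(lapply(truth$markers, function(m) m$b_specific))
  )
  pred_cons_a <- cons$gene_a[cons$class == "conserved" & !is.na(cons$gene_a)]
  pred_cons_b <- cons$gene_b[cons$class == "conserved" & !is.na(cons$gene_b)]
  pred_spec_a <- cons$gene_a[cons$class == "a_specific" & !is.na(cons$gene_a)]
  pred_spec_b <- cons$gene_b[cons$class == "b_specific" & !is.na(cons$gene_b)]
  pr <- function(pred, pos, neg) {
    judged <- intersect(pred, c(pos, neg))
    c(precision = if (length(judged)) mean(judged %in% pos) else NA_real_,
      recall = mean(pos %in% pred))
  }
  cons_pr_a <- pr(pred_cons_a, planted$cons_a, planted$spec_a)
  spec_pr_a <- pr(pred_spec_a, planted$spec_a, planted$cons_a)
  spec_pr_b <- pr(pred_spec_b, planted$spec_b, planted$cons_b)

  ranked <- res$analog_candidates
  planted_pairs <- paste(truth$analogs$gene_a, truth$analogs$gene_b)
  analog_recall <- mean(planted_pairs %in% paste(ranked$gene_a, ranked$gene_b))
  # orthologous pairs leaking through the inverse-bitscore analog filter
  cand_all <- filter_analog_candidates(res$pairs, unique(res$pairs$gene_b),
                                       res$config_a)
  hkey <- paste(truth$orthologs$gene_a, truth$orthologs$gene_b)
  n_ortholog_pass <- sum(paste(cand_all$gene_a, cand_all$gene_b) %in% hkey)

  list(
    ari_a = ari_a, ari_b = ari_b,
    spearman_a = sp_a, spearman_b = sp_b,
    sign_accuracy_a = sign_acc(res$traj_a, res$proc_a),
    sign_accuracy_b = sign_acc(res$traj_b, pm_b),
    conserved_precision = unname(cons_pr_a["precision"]),
    conserved_recall = unname(cons_pr_a["recall"]),
    a_specific_precision = unname(spec_pr_a["precision"]),
    a_specific_recall = unname(spec_pr_a["recall"]),
    b_specific_precision = unname(spec_pr_b["precision"]),
    b_specific_recall = unname(spec_pr_b["recall"]),
    analog_recall_topk = analog_recall,
    n_ortholog_pairs_passing_inverse_filter = n_ortholog_pass
  )
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_i <- sum(ch2(rowSums(tab)))
  sum_j <- sum(ch2(colSums(tab)))
  expected <- sum_i * sum_j / ch2(n)
  mx <- (sum_i + sum_j) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
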