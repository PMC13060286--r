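# shared fixtures; heavyweight objects are memoised per test run
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a CountMatrix built from a dense integer matrix
make_cm <- function(m, cell_ids = NULL, gene_ids = NULL, ...) {
  if (is.null(cell_ids)) cell_ids <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(ncol(m)))
  dimnames(m) <- list(cell_ids, gene_ids)
  count_matrix(m, ...)
}

# a ProcessedMatrix shell for unit tests that bypass the full chain
make_pm <- function(x, clusters = NULL, embedding = NULL, knn_k = NULL) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("c%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("g%02d", seq_len(ncol(x)))
  pm <- structure(list(x = methods::as(Matrix::Matrix(x, sparse = TRUE),
                                       "CsparseMatrix"),
                       cell_meta = data.frame(row.names = rownames(x)),
                       gene_meta = data.frame(row.names = colnames(x))),
                  class = "ProcessedMatrix")
  if (!is.null(embedding)) {
    rownames(embedding) <- rownames(x)
    pm$embedding <- embedding
    if (!is.null(knn_k)) pm <- build_knn(pm, k = knn_k)
  }
  if (!is.null(clusters)) pm$clusters <- setNames(clusters, rownames(x))
  pm
}

small_sim_config <- function(...) {
  sim_config(n_cells = 700, n_genes_a = 400, n_genes_b = 450,
             n_orthologs = 250, n_markers_per_state = 5,
             n_specific_per_state = 5, n_analogs = 3, n_gradient = 8,
             n_mito = 6, n_surface_extra = 12, ...)
}

small_pipe_config <- function(species, ...) {
  qc_preset(species, knn_k = 30, n_hvg = 300, max_components = 40,
            n_bins = 20, top_var_genes = 100, n_top_markers = 25,
            seed = 1, ...)
}

small_dataset <- function() {
  memo("small_dataset", {
    scfg <- small_sim_config()
    truth <- generate_truth(scfg, seed = 1)
    mats <- simulate_counts(truth, scfg, seed = 1)
    list(truth = truth, config = scfg,
         data = list(A = mats$A, B = mats$B,
                     homology = homology_table(
                       truth$orthologs[, c("gene_a", "gene_b", "bitscore")]),
                     surface = truth$surface_b,
                     categories = truth$categories_a))
  })
}

small_analysis <- function() {
  memo("small_analysis", {
    sd <- small_dataset()
    res <- suppressWarnings(
      analyze_dataset(sd$data, small_pipe_config("mouse"),
                      small_pipe_config("human")))
    list(res = res, truth = sd$truth)
  })
}

# the study-scale dataset and full analysis (spec default conditions, seed 0)
default_analysis <- function() {
  memo("default_analysis", {
    scfg <- sim_config()
    truth <- generate_truth(scfg, seed = 0)
    mats <- simulate_counts(truth, scfg, seed = 0)
    data <- list(A = mats$A, B = mats$B,
                 homology = homology_table(
                   truth$orthologs[, c("gene_a", "gene_b", "bitscore")]),
                 surface = truth$surface_b,
                 categories = truth$categories_a)
    res <- suppressWarnings(
      analyze_dataset(data, qc_preset("mouse"), qc_preset("human")))
    list(res = res, truth = truth,
         metrics = evaluate_against_truth(res, truth))
  })
}

# tiny dataset + config files for CLI round trips
tiny_cli_fixture <- function(root) {
  sim_yaml <- file.path(root, "sim.yaml")
  writeLines(c("n_cells: 400", "n_genes_a: 300", "n_genes_b: 330",
               "n_orthologs: 170", "n_markers_per_state: 4",
               "n_specific_per_state: 4", "n_analogs: 3", "n_gradient: 6",
               "n_mito: 6", "n_surface_extra: 8"), sim_yaml)
  pipe_yaml <- file.path(root, "pipe.yaml")
  writeLines(c("knn_k: 25", "n_hvg: 250", "max_components: 30",
               "n_bins: 15", "top_var_genes: 80", "n_top_markers: 20"),
             pipe_yaml)
  list(sim = sim_yaml, pipe = pipe_yaml)
}
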