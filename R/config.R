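#' Pipeline configuration
#'
#' Assembles and validates the full set of tunable parameters used across the
#' pipeline. Defaults follow the published analysis of two-species tubal
#' epithelium data: cells with more than 30% mitochondrial counts, fewer than
#' 750 total counts or fewer than 200 detected genes are discarded; principal
#' components are kept up to 95% of captured variance; the neighbour graph
#' uses k = 70; Louvain resolution is 0.7; signed pseudotime is cut into 40
#' equal-count bins; homologous gene pairs align at correlation > 0.2; analog
#' candidates require correlation > 0.4 and inverse BLAST bitscore > 0.010;
#' the final ranked list keeps the top 10.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `PipelineConfig` (a validated named list) with
#'   elements:
#' \describe{
#'   \item{mito_max}{maximum mitochondrial count fraction, default 0.30.}
#'   \item{min_counts}{minimum total counts per cell, default 750.}
#'   \item{min_features}{minimum detected genes per cell, default 200.}
#'   \item{scale}{normalisation scale factor, default 1e4.}
#'   \item{n_hvg}{number of highly variable genes, default 2000.}
#'   \item{variance_target}{cumulative explained-variance target, default 0.95.}
#'   \item{max_components}{maximum number of principal components, default 100.}
#'   \item{knn_k}{within-species nearest-neighbour count, default 70.}
#'   \item{k_cross}{cross-species nearest-neighbour count, default 20.}
#'   \item{cluster_resolution}{community-detection resolution, default 0.7.}
#'   \item{n_bins}{number of pseudotime bins, default 40.}
#'   \item{conservation_corr_min}{correlation floor separating conserved from
#'     species-specific markers, default 0.2.}
#'   \item{analog_corr_min}{correlation floor for analog candidates,
#'     default 0.4.}
#'   \item{inv_bitscore_min}{inverse-bitscore floor for analog candidates,
#'     default 0.010.}
#'   \item{top_k}{number of ranked analog candidates emitted, default 10.}
#'   \item{r_max}{rank cap of the signature score, default 1500.}
#'   \item{n_top_markers}{markers taken per cell state for the conservation
#'     reference, default 40.}
#'   \item{top_var_genes}{per-species size of the top-variable gene set whose
#'     cross product seeds non-homologous candidate pairs, default 250.}
#'   \item{mito_prefixes}{gene-name prefixes marking mitochondrial genes.}
#'   \item{seed}{base random seed, default 0.}
#' }
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mito_max = 0.30,
    min_counts = 750L,
    min_features = 200L,
    scale = 1e4,
    n_hvg = 2000L,
    variance_target = 0.95,
    max_components = 100L,
    knn_k = 70L,
    k_cross = 20L,
    cluster_resolution = 0.7,
    n_bins = 40L,
    conservation_corr_min = 0.2,
    analog_corr_min = 0.4,
    inv_bitscore_min = 0.010,
    top_k = 10L,
    r_max = 1500L,
    n_top_markers = 40L,
    top_var_genes = 250L,
    mito_prefixes = c("mt-", "MT-"),
    seed = 0L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stopf("all configuration overrides must be named")
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
    }
    cfg <- modifyList(cfg, dots)
  }
  validate_config(cfg)
  int_keys <- c("min_counts", "min_features", "n_hvg", "max_components",
                "knn_k", "k_cross", "n_bins", "top_k", "r_max",
                "n_top_markers", "top_var_genes", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  structure(cfg, class = "PipelineConfig")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, why) {
    if (!isTRUE(ok)) stopf("invalid configuration value for '%s': %s", key, why)
  }
  frac <- function(key) {
    v <- cfg[[key]]
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1, key,
        "must be a fraction in [0, 1]")
  }
  nonneg_int <- function(key) {
    v <- cfg[[key]]
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v == floor(v), key,
        "must be a non-negative integer")
  }
  frac("mito_max"); frac("variance_target")
  nonneg_int("min_counts"); nonneg_int("min_features"); nonneg_int("n_hvg")
  nonneg_int("max_components"); nonneg_int("knn_k"); nonneg_int("k_cross")
  nonneg_int("top_k"); nonneg_int("r_max"); nonneg_int("n_top_markers")
  nonneg_int("top_var_genes"); nonneg_int("seed")
  chk(is.numeric(cfg$n_bins) && cfg$n_bins >= 2 && cfg$n_bins == floor(cfg$n_bins),
      "n_bins", "must be an integer >= 2")
  chk(is.numeric(cfg$scale) && cfg$scale > 0, "scale", "must be positive")
  chk(is.numeric(cfg$cluster_resolution) && cfg$cluster_resolution > 0,
      "cluster_resolution", "must be positive")
  for (k in c("conservation_corr_min", "analog_corr_min")) {
    v <- cfg[[k]]
    chk(is.numeric(v) && length(v) == 1 && v >= -1 && v <= 1, k,
        "must be a correlation in [-1, 1]")
  }
  chk(is.numeric(cfg$inv_bitscore_min) && cfg$inv_bitscore_min >= 0,
      "inv_bitscore_min", "must be non-negative")
  chk(is.character(cfg$mito_prefixes) && length(cfg$mito_prefixes) >= 1,
      "mito_prefixes", "must be a non-empty character vector")
  invisible(TRUE)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file take their documented defaults; unknown keys and
#' out-of-range values are rejected with the offending key named. The
#' effective configuration is echoed to the log at info level.
#'
#' @param path path to a YAML key-value file; `NULL` or a missing/empty file
#'   yields the all-defaults configuration.
#' @return a [pipeline_config()] object.
#' @export
load_config <- function(path = NULL) {
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("configuration file not found: %s", path)
    raw <- yaml::read_yaml(path)
    if (!is.null(raw)) {
      if (!is.list(raw)) stopf("configuration file must be a YAML mapping")
      overrides <- raw
    }
  }
  cfg <- do.call(pipeline_config, overrides)
  am_log("info", "effective config: %s",
         paste(sprintf("%s=%s", names(cfg),
                       vapply(cfg, function(v) paste(format(v), collapse = ","),
                              character(1))),
               collapse = " "))
  cfg
}

#' Species quality-control presets
#'
#' The mouse preset removes cells with more than 30% mitochondrial counts,
#' fewer than 750 total counts or fewer than 200 detected genes. The human
#' preset tightens the mitochondrial ceiling to 20% and keeps the same count
#' and feature floors.
#'
#' @param species `"mouse"` or `"human"`.
#' @param ... further overrides passed to [pipeline_config()].
#' @return a [pipeline_config()] object.
#' @export
qc_preset <- function(species = c("mouse", "human"), ...) {
  species <- match.arg(species)
  mito <- if (species == "human") 0.20 else 0.30
  pipeline_config(mito_max = mito, ...)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
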