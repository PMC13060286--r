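#' Configuration of the two-species synthetic dataset
#'
#' The generator emulates the structure the analysis assumes: two species
#' whose tubal-epithelium-like cells differentiate from a bipotent progenitor
#' either to a secretory fate or through a pre-ciliated intermediate to a
#' ciliated fate; a one-to-one ortholog map with BLAST-like bitscores;
#' planted conserved and species-specific markers per cell state; and planted
#' analogous gene pairs that share the progenitor-restricted expression
#' program in both species but have no homology record at all.
#'
#' @param ... named overrides of the defaults below.
#' @return an object of class `SimConfig`, a validated named list:
#' \describe{
#'   \item{n_cells}{cells per species, default 3000.}
#'   \item{n_genes_a,n_genes_b}{genes per species, defaults 1500 / 1800.}
#'   \item{n_orthologs}{one-to-one ortholog pairs, default 1000.}
#'   \item{n_markers_per_state}{planted conserved markers per state, default 10.}
#'   \item{n_specific_per_state}{planted species-specific markers per state and
#'     species, default 10.}
#'   \item{n_analogs}{planted analogous pairs, default 5.}
#'   \item{low_quality_frac}{fraction of planted low-quality cells, default 0.05.}
#'   \item{dispersion}{negative-binomial dispersion, default 0.3.}
#'   \item{library_median,library_sdlog}{log-normal library-size law for good
#'     cells, defaults 5000 / 0.35.}
#'   \item{lowq_library_median}{library-size median of low-quality cells,
#'     default 300 (capped at 600 so the count floor is always violated).}
#'   \item{mito_frac,lowq_mito_frac}{target mitochondrial fractions of good and
#'     low-quality cells, defaults 0.07 / 0.5.}
#'   \item{n_mito}{mitochondrial genes per species, default 10.}
#'   \item{n_gradient}{staggered-onset differentiation genes per branch,
#'     default 12 (shared ortholog programs; they give the transcriptome a
#'     continuous gradient along each branch).}
#'   \item{n_surface_extra}{surface-flagged species-B genes beyond the analog
#'     partners, default 40 (half drawn from orthologous genes).}
#'   \item{state_props}{latent-state proportions (progenitor, secretory,
#'     pre_ciliated, ciliated), default (0.30, 0.30, 0.15, 0.25).}
#'   \item{marker_amp,gradient_amp,baseline_sdlog}{program amplitudes and
#'     baseline spread of relative expression.}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_cells = 3000L,
    n_genes_a = 1500L,
    n_genes_b = 1800L,
    n_orthologs = 1000L,
    n_markers_per_state = 10L,
    n_specific_per_state = 10L,
    n_analogs = 5L,
    low_quality_frac = 0.05,
    dispersion = 0.3,
    library_median = 5000,
    library_sdlog = 0.35,
    lowq_library_median = 300,
    mito_frac = 0.07,
    lowq_mito_frac = 0.5,
    n_mito = 10L,
    n_gradient = 12L,
    n_surface_extra = 40L,
    state_props = c(progenitor = 0.30, secretory = 0.30,
                    pre_ciliated = 0.15, ciliated = 0.25),
    marker_amp = 6,
    gradient_amp = 3,
    baseline_sdlog = 1
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      stopf("unknown or unnamed sim_config key(s): %s",
            paste(unknown, collapse = ", "))
    }
    cfg <- modifyList(cfg, dots)
  }
  if (abs(sum(cfg$state_props) - 1) > 1e-8) stopf("state_props must sum to 1")
  if (cfg$low_quality_frac < 0 || cfg$low_quality_frac > 0.5) {
    stopf("low_quality_frac must be in [0, 0.5]")
  }
  n_marked <- 4L * (cfg$n_markers_per_state + 2L * cfg$n_specific_per_state) +
    2L * cfg$n_gradient + 1L
  if (n_marked > cfg$n_orthologs) {
    stopf("planted marker counts exceed the ortholog pool (%d needed, %d available)",
          n_marked, cfg$n_orthologs)
  }
  if (cfg$n_orthologs + cfg$n_analogs + cfg$n_mito > min(cfg$n_genes_a, cfg$n_genes_b)) {
    stopf("requested gene roles exceed n_genes")
  }
  for (k in c("n_cells", "n_genes_a", "n_genes_b", "n_orthologs",
              "n_markers_per_state", "n_specific_per_state", "n_analogs",
              "n_mito", "n_gradient", "n_surface_extra")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  structure(cfg, class = "SimConfig")
}

.states <- c("progenitor", "secretory", "pre_ciliated", "ciliated")

# exact integer split of n into proportions (largest remainder)
split_counts <- function(n, props) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# latent cells of one species: state, lineage branch, latent time t
sample_cells <- function(cfg, species) {
  n <- cfg$n_cells
  n_low <- as.integer(round(n * cfg$low_quality_frac))
  n_good <- n - n_low
  counts <- split_counts(n_good, cfg$state_props)
  base_state <- c(rep(.states, counts),
                  sample(.states, n_low, replace = TRUE, prob = cfg$state_props))
  low <- c(rep(FALSE, n_good), rep(TRUE, n_low))
  ord <- sample.int(n)
  base_state <- base_state[ord]; low <- low[ord]
  t <- numeric(n)
  t[base_state == "progenitor"] <- runif(sum(base_state == "progenitor"), 0, 0.25)
  t[base_state == "secretory"] <- runif(sum(base_state == "secretory"), 0.25, 1)
  t[base_state == "pre_ciliated"] <- runif(sum(base_state == "pre_ciliated"), 0.28, 0.62)
  t[base_state == "ciliated"] <- runif(sum(base_state == "ciliated"), 0.62, 1)
  branch <- ifelse(base_state == "secretory", "secretory",
                   ifelse(base_state %in% c("pre_ciliated", "ciliated"),
                          "ciliogenic", NA))
  ip <- which(base_state == "progenitor")
  branch[ip] <- sample(c("secretory", "ciliogenic"), length(ip), replace = TRUE)
  data.frame(
    cell_id = sprintf("%s_cell%04d", species, seq_len(n)),
    state = ifelse(low, "low_quality", base_state),
    base_state = base_state,
    branch = branch,
    t = t,
    low_quality = low,
    stringsAsFactors = FALSE
  )
}

# one species' gene program table; `program` rows describe shared programs to
# copy (for orthologs) or NA to draw fresh
new_gene_table <- function(gene_ids, cfg) {
  n <- length(gene_ids)
  data.frame(
    gene_id = gene_ids,
    role = rep("background", n),
    state = NA_character_,
    shape = rep("flat", n),
    branch = NA_character_,
    t0 = NA_real_, t1 = NA_real_, t2 = NA_real_, slope = NA_real_,
    e0 = NA_real_, e1 = NA_real_, e_branch = NA_character_, e_w = NA_real_,
    amp = 0,
    baseline = rlnorm(n, meanlog = 0, sdlog = cfg$baseline_sdlog),
    is_mito = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

# draw program parameters for one planted gene of a given state
draw_program <- function(state, cfg) {
  amp <- runif(1, 0.7, 1.3) * cfg$marker_amp
  switch(state,
    progenitor = list(shape = "fall", branch = NA, t0 = runif(1, 0.10, 0.30),
                      t1 = NA, slope = 0.06, amp = amp),
    secretory = list(shape = "rise", branch = "secretory",
                     t0 = runif(1, 0.40, 0.60), t1 = NA, slope = 0.08, amp = amp),
    pre_ciliated = list(shape = "bump", branch = "ciliogenic",
                        t0 = runif(1, 0.28, 0.32), t1 = runif(1, 0.60, 0.64),
                        slope = 0.05, amp = amp),
    ciliated = list(shape = "rise", branch = "ciliogenic",
                    t0 = runif(1, 0.60, 0.72), t1 = NA, slope = 0.06, amp = amp)
  )
}

set_program <- function(genes, idx, role, state, prog) {
  genes$role[idx] <- role
  genes$state[idx] <- if (is.null(state)) NA_character_ else state
  genes$shape[idx] <- prog$shape
  genes$branch[idx] <- if (is.null(prog$branch) || is.na(prog$branch)) NA_character_ else prog$branch
  genes$t0[idx] <- prog$t0
  for (f in c("t1", "t2", "e0", "e1", "e_w")) {
    genes[[f]][idx] <- if (is.null(prog[[f]])) NA_real_ else prog[[f]]
  }
  genes$e_branch[idx] <- if (is.null(prog$e_branch)) NA_character_ else prog$e_branch
  genes$slope[idx] <- prog$slope
  genes$amp[idx] <- prog$amp
  genes$baseline[idx] <- runif(1, 0.5, 1.5) * 0.5
  genes
}

#' Generate the latent ground truth of a two-species synthetic dataset
#'
#' Deterministic for a fixed seed. Gene programs are logistic activation (or
#' deactivation) curves over latent time with branch-specific modules;
#' orthologous planted markers share program parameters exactly, planted
#' species-specific markers carry the program in exactly one species (their
#' ortholog partner stays at background), and planted analog pairs share the
#' progenitor-restricted decaying program in both species while being absent
#' from the homology table. A designated "program handoff" ortholog pair
#' (an early-ciliogenic gene switching off as a late-ciliated marker switches
#' on) emulates the sequential activation seen along ciliogenesis.
#'
#' @param config a [sim_config()].
#' @param seed integer random seed.
#' @return an object of class `SyntheticTruth`: a list with elements
#'   `config`, `cells` (per-species latent cell tables), `genes` (per-species
#'   program tables), `orthologs` (gene_a, gene_b, bitscore, divergent),
#'   `markers` (per state: conserved pair table, a_specific, b_specific),
#'   `analogs` (gene_a, gene_b), `handoff` (early/late gene per species),
#'   `surface_b`, `categories_a` (gene -> functional category map) and
#'   `qc_violations` (per-species cell ids planted to fail QC).
#' @export
generate_truth <- function(config = sim_config(), seed = 0L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(as.integer(seed))
  cfg <- config

  cells <- list(A = sample_cells(cfg, "spA"), B = sample_cells(cfg, "spB"))

  ids_a <- c(sprintf("mt-ga%02d", seq_len(cfg$n_mito)),
             sprintf("gA%04d", seq_len(cfg$n_genes_a - cfg$n_mito)))
  ids_b <- c(sprintf("MT-GB%02d", seq_len(cfg$n_mito)),
             sprintf("gB%04d", seq_len(cfg$n_genes_b - cfg$n_mito)))
  genes_a <- new_gene_table(ids_a, cfg)
  genes_b <- new_gene_table(ids_b, cfg)
  genes_a$is_mito <- is_mito_gene(ids_a)
  genes_b$is_mito <- is_mito_gene(ids_b)

  # ortholog pairing: random one-to-one among non-mito genes
  pool_a <- sample(which(!genes_a$is_mito), cfg$n_orthologs)
  pool_b <- sample(which(!genes_b$is_mito), cfg$n_orthologs)
  orth <- data.frame(ia = pool_a, ib = pool_b, divergent = FALSE)

  take <- function(n) {
    idx <- seq_len(n)
    out <- orth_free[idx]
    orth_free <<- orth_free[-idx]
    out
  }
  orth_free <- sample(seq_len(cfg$n_orthologs))

  markers <- list()
  for (s in .states) {
    cons <- take(cfg$n_markers_per_state)
    for (r in cons) {
      prog <- draw_program(s, cfg)
      genes_a <- set_program(genes_a, orth$ia[r], "conserved_marker", s, prog)
      genes_b <- set_program(genes_b, orth$ib[r], "conserved_marker", s, prog)
    }
    a_spec <- take(cfg$n_specific_per_state)
    for (r in a_spec) {
      genes_a <- set_program(genes_a, orth$ia[r], "a_specific_marker", s,
                             draw_program(s, cfg))
      # divergent orthologs carry independent programs: the partner follows
      # a different state's module, not a silenced copy
      s2 <- sample(setdiff(.states, s), 1)
      genes_b <- set_program(genes_b, orth$ib[r], "divergent_partner", s2,
                             draw_program(s2, cfg))
      orth$divergent[r] <- TRUE
    }
    b_spec <- take(cfg$n_specific_per_state)
    for (r in b_spec) {
      genes_b <- set_program(genes_b, orth$ib[r], "b_specific_marker", s,
                             draw_program(s, cfg))
      s2 <- sample(setdiff(.states, s), 1)
      genes_a <- set_program(genes_a, orth$ia[r], "divergent_partner", s2,
                             draw_program(s2, cfg))
      orth$divergent[r] <- TRUE
    }
    markers[[s]] <- list(
      conserved = data.frame(gene_a = ids_a[orth$ia[cons]],
                             gene_b = ids_b[orth$ib[cons]],
                             stringsAsFactors = FALSE),
      a_specific = ids_a[orth$ia[a_spec]],
      b_specific = ids_b[orth$ib[b_spec]]
    )
  }

  # staggered-onset gradient genes make latent time identifiable everywhere
  for (br in c("secretory", "ciliogenic")) {
    onsets <- seq(0.25, 0.9, length.out = cfg$n_gradient)
    g_idx <- take(cfg$n_gradient)
    for (j in seq_along(g_idx)) {
      prog <- list(shape = "rise", branch = br, t0 = onsets[j], t1 = NA,
                   slope = 0.12, amp = runif(1, 0.7, 1.3) * cfg$gradient_amp)
      r <- g_idx[j]
      genes_a <- set_program(genes_a, orth$ia[r], "gradient", NA, prog)
      genes_b <- set_program(genes_b, orth$ib[r], "gradient", NA, prog)
    }
  }

  # early-ciliogenic -> late-ciliated program handoff pair
  ho <- take(1L)
  ho_prog <- list(shape = "fall_branch", branch = "ciliogenic", t0 = 0.62,
                  t1 = NA, slope = 0.05, amp = 0.8 * cfg$marker_amp)
  genes_a <- set_program(genes_a, orth$ia[ho], "handoff_early", NA, ho_prog)
  genes_b <- set_program(genes_b, orth$ib[ho], "handoff_early", NA, ho_prog)
  handoff <- list(
    A = c(early = ids_a[orth$ia[ho]], late = markers$ciliated$conserved$gene_a[1]),
    B = c(early = ids_b[orth$ib[ho]], late = markers$ciliated$conserved$gene_b[1])
  )

  # remaining ortholog pairs: shared background baselines (conserved noise)
  for (r in orth_free) {
    genes_b$baseline[orth$ib[r]] <- genes_a$baseline[orth$ia[r]]
  }

  # planted analogs: each pair shares, exactly, its own progenitor-phase
  # transient program (a staggered early expression window with per-branch
  # offsets; the earliest windows add a small pair-specific late echo on one
  # branch). Staggering keeps the programs pairwise distinguishable by
  # expression correlation — unlike identical monotone decays, whose shared
  # on-set makes every progenitor gene look alike — while all pairs remain
  # progenitor-enriched. Amplitudes are uniform across the analog set.
  an_a <- sample(setdiff(which(!genes_a$is_mito), orth$ia), cfg$n_analogs)
  an_b <- sample(setdiff(which(!genes_b$is_mito), orth$ib), cfg$n_analogs)
  lobes <- list(c("secretory", 0.28, 0.48), c("ciliogenic", 0.28, 0.48),
                c("secretory", 0.75, 0.95), c("ciliogenic", 0.75, 0.95),
                c("both", 0.45, 0.62), c("both", 0.72, 0.90))
  for (j in seq_len(cfg$n_analogs)) {
    prog <- list(shape = "window", branch = NA,
                 t0 = 0, t1 = 0.22, t2 = 0.22,
                 slope = 0.04, amp = cfg$marker_amp)
    lb <- lobes[[(j - 1) %% length(lobes) + 1]]
    prog$e0 <- as.numeric(lb[2])
    prog$e1 <- as.numeric(lb[3])
    prog$e_branch <- lb[1]
    prog$e_w <- 0.9
    genes_a <- set_program(genes_a, an_a[j], "analog", "progenitor", prog)
    genes_b <- set_program(genes_b, an_b[j], "analog", "progenitor", prog)
  }
  analogs <- data.frame(gene_a = ids_a[an_a], gene_b = ids_b[an_b],
                        stringsAsFactors = FALSE)

  # bitscores: log-normal, median ~200, truncated at 120 so orthologs are
  # unambiguous matches (inverse bitscore < 1/120 < 0.010)
  bits <- rlnorm(cfg$n_orthologs, meanlog = log(200), sdlog = 0.25)
  bits <- pmax(bits, 120)
  orthologs <- data.frame(gene_a = ids_a[orth$ia], gene_b = ids_b[orth$ib],
                          bitscore = bits, divergent = orth$divergent,
                          stringsAsFactors = FALSE)

  # surface annotation on species B: analog partners, some orthologs, some
  # background genes
  n_half <- cfg$n_surface_extra %/% 2L
  surf_orth <- ids_b[sample(orth$ib, min(n_half, length(orth$ib)))]
  bg_b <- setdiff(which(!genes_b$is_mito), c(orth$ib, an_b))
  surf_bg <- ids_b[sample(bg_b, min(cfg$n_surface_extra - n_half, length(bg_b)))]
  surface_b <- sort(unique(c(analogs$gene_b, surf_orth, surf_bg)))

  # functional-category map over species-A genes (generic two-column map)
  cat_df <- rbind(
    data.frame(gene = markers$ciliated$conserved$gene_a, category = "ciliogenesis"),
    data.frame(gene = markers$secretory$conserved$gene_a, category = "secretion"),
    data.frame(gene = c(markers$progenitor$conserved$gene_a, analogs$gene_a),
               category = "stemness"),
    data.frame(gene = ids_a[sample(setdiff(which(genes_a$role == "background" &
                                                   !genes_a$is_mito), orth$ia), 20)],
               category = "housekeeping")
  )

  truth <- list(
    config = cfg,
    cells = cells,
    genes = list(A = genes_a, B = genes_b),
    orthologs = orthologs,
    markers = markers,
    analogs = analogs,
    handoff = handoff,
    surface_b = surface_b,
    categories_a = cat_df,
    qc_violations = list(A = cells$A$cell_id[cells$A$low_quality],
                         B = cells$B$cell_id[cells$B$low_quality])
  )
  class(truth) <- "SyntheticTruth"
  truth
}

# relative (pre-normalisation) program intensity for one species
program_intensity <- function(genes, cells) {
  n <- nrow(cells); g <- nrow(genes)
  t <- cells$t
  br <- cells$branch
  out <- matrix(rep(genes$baseline, each = n), nrow = n, ncol = g,
                dimnames = list(cells$cell_id, genes$gene_id))
  active <- which(genes$shape != "flat" & !genes$is_mito)
  for (j in active) {
    sh <- genes$shape[j]
    onb <- if (is.na(genes$branch[j])) rep(TRUE, n) else br == genes$branch[j]
    curve <- switch(sh,
      fall = 1 - plogis((t - genes$t0[j]) / genes$slope[j]),
      rise = plogis((t - genes$t0[j]) / genes$slope[j]),
      bump = plogis((t - genes$t0[j]) / genes$slope[j]) -
             plogis((t - genes$t1[j]) / genes$slope[j]),
      fall_branch = 1 - plogis((t - genes$t0[j]) / genes$slope[j]),
      fall2 = {
        mid <- ifelse(br == "secretory", genes$t0[j], genes$t1[j])
        1 - plogis((t - mid) / genes$slope[j])
      },
      window = {
        end <- ifelse(br == "secretory", genes$t1[j], genes$t2[j])
        v <- plogis((t - genes$t0[j]) / genes$slope[j]) -
          plogis((t - end) / genes$slope[j])
        if (!is.na(genes$e_w[j])) {
          onb <- if (genes$e_branch[j] == "both") TRUE else br == genes$e_branch[j]
          v <- v + genes$e_w[j] *
            (plogis((t - genes$e0[j]) / 0.05) -
               plogis((t - genes$e1[j]) / 0.05)) * onb
        }
        v
      })
    out[, j] <- genes$baseline[j] + genes$amp[j] * curve * onb
  }
  out
}

#' Simulate counts for both species from a SyntheticTruth
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `library_size x relative program intensity` and the configured dispersion.
#' Mitochondrial intensity is budgeted per cell so that good cells sit at the
#' configured mitochondrial fraction and planted low-quality cells exceed it;
#' low-quality cells additionally get library sizes far below the count
#' floor, so each planted low-quality cell violates at least one QC predicate.
#'
#' @param truth a [generate_truth()] result.
#' @param config the same [sim_config()] used for the truth.
#' @param seed integer random seed (independent of the truth seed).
#' @return named list of two [count_matrix()] objects (`A`, `B`) whose
#'   `cell_meta` carries `species`, `true_state`, `true_time`, `true_branch`
#'   and whose `gene_meta` carries `is_mito` (and `is_surface` for B).
#' @export
simulate_counts <- function(truth, config = truth$config, seed = 0L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(as.integer(seed) + 1L)
  cfg <- config
  out <- list()
  for (sp in c("A", "B")) {
    cells <- truth$cells[[sp]]
    genes <- truth$genes[[sp]]
    n <- nrow(cells)
    inten <- program_intensity(genes, cells)
    # mitochondrial budget: fraction f of total intensity per cell
    f <- ifelse(cells$low_quality, cfg$lowq_mito_frac, cfg$mito_frac)
    mi <- which(genes$is_mito)
    w <- rlnorm(length(mi), 0, 0.5)
    w <- w / sum(w)
    s_rest <- rowSums(inten[, -mi, drop = FALSE])
    inten[, mi] <- outer(s_rest * f / (1 - f), w)
    p <- inten / rowSums(inten)
    lib <- ifelse(cells$low_quality,
                  pmin(600, rlnorm(n, log(cfg$lowq_library_median), 0.3)),
                  rlnorm(n, log(cfg$library_median), cfg$library_sdlog))
    mu <- p * lib
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = 1 / cfg$dispersion),
                     nrow = n, dimnames = dimnames(mu))
    cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                       cell_meta = data.frame(
                         species = sp,
                         true_state = cells$state,
                         true_time = cells$t,
                         true_branch = cells$branch,
                         row.names = cells$cell_id),
                       gene_meta = data.frame(
                         is_mito = genes$is_mito,
                         row.names = genes$gene_id))
    if (sp == "B") {
      cm$gene_meta$is_surface <- gene_ids(cm) %in% truth$surface_b
    }
    out[[sp]] <- cm
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Emits both species as 10x-style MTX triplets (`species_a/`, `species_b/`),
#' the ortholog map as BLAST outfmt-6 (`homology.tsv`), the surface-marker
#' list (`surface_markers.txt`), per-state conserved marker signatures
#' (`signatures.tsv`), the gene-to-category map (`gene_categories.tsv`) and a
#' machine-readable `truth.json`.
#'
#' @param matrices result of [simulate_counts()].
#' @param truth the matching [generate_truth()] result.
#' @param out_dir output directory.
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(matrices, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_mtx(matrices$A, file.path(out_dir, "species_a"))
  write_counts_mtx(matrices$B, file.path(out_dir, "species_b"))
  ht <- homology_table(truth$orthologs[, c("gene_a", "gene_b", "bitscore")])
  write_blast6(ht, file.path(out_dir, "homology.tsv"))
  writeLines(truth$surface_b, file.path(out_dir, "surface_markers.txt"))
  sig <- do.call(rbind, lapply(.states, function(s) {
    data.frame(signature = paste0(s, "_program"),
               gene = truth$markers[[s]]$conserved$gene_a)
  }))
  write_tsv(sig, file.path(out_dir, "signatures.tsv"))
  write_tsv(truth$categories_a, file.path(out_dir, "gene_categories.tsv"))
  tr <- truth
  tr$config <- unclass(tr$config)
  class(tr) <- NULL
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  paths <- c(species_a = file.path(out_dir, "species_a"),
             species_b = file.path(out_dir, "species_b"),
             homology = file.path(out_dir, "homology.tsv"),
             surface = file.path(out_dir, "surface_markers.txt"),
             signatures = file.path(out_dir, "signatures.tsv"),
             categories = file.path(out_dir, "gene_categories.tsv"),
             truth = file.path(out_dir, "truth.json"))
  invisible(paths)
}

#' Read back a written truth.json
#'
#' @param path path to `truth.json`.
#' @return a `SyntheticTruth`-shaped list (data frames restored).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(tr) <- "SyntheticTruth"
  tr
}
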