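#' Construct a CountMatrix
#'
#' The package's container for one species' raw counts: a sparse cells x
#' genes matrix of non-negative integers with per-cell and per-gene metadata.
#'
#' @param counts a matrix or `Matrix::sparseMatrix` (cells x genes) of
#'   non-negative integer counts, with unique row (cell) and column (gene)
#'   names unless `cell_ids`/`gene_ids` are given.
#' @param cell_ids,gene_ids optional id vectors overriding dimnames.
#' @param cell_meta,gene_meta optional data frames of per-cell / per-gene
#'   metadata; rows are matched to ids by rowname or recycled in order.
#' @return an object of class `CountMatrix`: a list with elements `counts`
#'   (`dgCMatrix`), `cell_meta`, `gene_meta` (data frames keyed by id).
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                         cell_meta = NULL, gene_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stopf("cell and gene ids are required (as dimnames or arguments)")
  }
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts)) {
    stopf("id vectors (%d cells, %d genes) do not match counts dimensions %d x %d",
          length(cell_ids), length(gene_ids), nrow(counts), ncol(counts))
  }
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v)))) {
    stopf("counts must be non-negative integers")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(cell_meta)) cell_meta <- data.frame(row.names = cell_ids)
  if (is.null(gene_meta)) gene_meta <- data.frame(row.names = gene_ids)
  cell_meta <- as.data.frame(cell_meta)
  gene_meta <- as.data.frame(gene_meta)
  if (nrow(cell_meta) != length(cell_ids)) stopf("cell_meta has wrong row count")
  if (nrow(gene_meta) != length(gene_ids)) stopf("gene_meta has wrong row count")
  rownames(cell_meta) <- cell_ids
  rownames(gene_meta) <- gene_ids
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (ncol(x$cell_meta)) {
    cat("  cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  }
  if (ncol(x$gene_meta)) {
    cat("  gene_meta:", paste(names(x$gene_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname count_matrix
#' @param cm a `CountMatrix`.
#' @export
cell_ids <- function(cm) rownames(cm$counts)

#' @rdname count_matrix
#' @export
gene_ids <- function(cm) colnames(cm$counts)

#' Flag mitochondrial genes by name prefix
#'
#' The deposited data do not carry an explicit mitochondrial annotation, so
#' genes are flagged by name prefix ("mt-" for mouse-style, "MT-" for
#' human-style symbols by default).
#'
#' @param gene_ids_vec character vector of gene names.
#' @param prefixes character vector of prefixes; a gene matching any prefix
#'   is flagged.
#' @return logical vector.
#' @export
is_mito_gene <- function(gene_ids_vec, prefixes = c("mt-", "MT-")) {
  hit <- rep(FALSE, length(gene_ids_vec))
  for (p in prefixes) {
    hit <- hit | startsWith(gene_ids_vec, p)
  }
  hit
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx` (genes x cells, coordinate format), `barcodes.tsv`
#' (one cell barcode per line) and `features.tsv` (gene id in the first
#' column). The matrix is transposed to the package's internal cells x genes
#' orientation. Optional `cell_meta.tsv` / `gene_meta.tsv` files (tab
#' separated, first column the id) are attached as metadata, so that
#' [write_counts_mtx()] round-trips exactly.
#'
#' @param directory path containing the triplet.
#' @param mito_prefixes prefixes used to populate `gene_meta$is_mito`.
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(directory, mito_prefixes = c("mt-", "MT-")) {
  need <- file.path(directory, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stopf("missing file(s): %s", paste(miss, collapse = ", "))
  m <- Matrix::readMM(need[1])
  barcodes <- readLines(need[2])
  feat <- read.delim(need[3], header = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(feat[[1]])
  if (nrow(m) != length(genes)) {
    stopf("matrix header declares %d genes but features.tsv has %d lines",
          nrow(m), length(genes))
  }
  if (ncol(m) != length(barcodes)) {
    stopf("matrix header declares %d cells but barcodes.tsv has %d lines",
          ncol(m), length(barcodes))
  }
  counts <- Matrix::t(m)
  cm <- count_matrix(counts, cell_ids = barcodes, gene_ids = genes)
  cm$gene_meta$is_mito <- is_mito_gene(genes, mito_prefixes)
  cmeta_path <- file.path(directory, "cell_meta.tsv")
  if (file.exists(cmeta_path)) {
    meta <- read.delim(cmeta_path, stringsAsFactors = FALSE)
    rownames(meta) <- meta[[1]]
    meta <- meta[barcodes, -1, drop = FALSE]
    cm$cell_meta <- cbind(cm$cell_meta, meta)
  }
  gmeta_path <- file.path(directory, "gene_meta.tsv")
  if (file.exists(gmeta_path)) {
    meta <- read.delim(gmeta_path, stringsAsFactors = FALSE)
    rownames(meta) <- meta[[1]]
    meta <- meta[genes, -1, drop = FALSE]
    keep <- setdiff(names(meta), "is_mito")
    cm$gene_meta[keep] <- meta[keep]
    if ("is_mito" %in% names(meta)) cm$gene_meta$is_mito <- as.logical(meta$is_mito)
  }
  cm
}

#' Write a CountMatrix as a 10x-style triplet
#'
#' Emits `matrix.mtx` in genes x cells orientation plus `barcodes.tsv` and
#' `features.tsv`, and (when metadata columns exist) `cell_meta.tsv` /
#' `gene_meta.tsv`, such that [read_counts_mtx()] reproduces the object.
#'
#' @param cm a `CountMatrix`.
#' @param directory output directory, created if needed.
#' @return `directory`, invisibly.
#' @export
write_counts_mtx <- function(cm, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(cm$counts), file.path(directory, "matrix.mtx"))
  writeLines(cell_ids(cm), file.path(directory, "barcodes.tsv"))
  writeLines(gene_ids(cm), file.path(directory, "features.tsv"))
  if (ncol(cm$cell_meta)) {
    df <- cbind(data.frame(cell_id = cell_ids(cm)), cm$cell_meta)
    write_tsv(df, file.path(directory, "cell_meta.tsv"))
  }
  if (ncol(cm$gene_meta)) {
    df <- cbind(data.frame(gene_id = gene_ids(cm)), cm$gene_meta)
    write_tsv(df, file.path(directory, "gene_meta.tsv"))
  }
  invisible(directory)
}

#' Subset a CountMatrix
#'
#' @param cm a `CountMatrix`.
#' @param cells,genes index, logical or id vectors; `NULL` keeps all.
#' @return a `CountMatrix`.
#' @export
subset_cells <- function(cm, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(cm$counts))
  if (is.null(genes)) genes <- seq_len(ncol(cm$counts))
  count_matrix(cm$counts[cells, genes, drop = FALSE],
               cell_meta = cm$cell_meta[cells, , drop = FALSE],
               gene_meta = cm$gene_meta[genes, , drop = FALSE])
}
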