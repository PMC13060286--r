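#' Read a BLAST tabular (outfmt 6) homology table
#'
#' Parses the standard 12-column tab-separated BLAST output (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' skipping `#` comment lines, and reduces to the best hit: for every
#' (gene_a, gene_b) pair only the record with the maximal bitscore is kept.
#' The reduction is idempotent.
#'
#' @param path path to the outfmt-6 file.
#' @return a data frame of class `HomologyTable` with columns `gene_a`,
#'   `gene_b`, `pident`, `evalue`, `bitscore`.
#' @export
read_blast6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(homology_table(data.frame(gene_a = character(), gene_b = character(),
                                     pident = numeric(), evalue = numeric(),
                                     bitscore = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols != 12L)
  if (length(bad)) {
    stopf("line %d: expected 12 tab-separated columns, found %d",
          lineno[bad[1]], ncols[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  pident <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(bitscore)) {
    stopf("line %d: non-numeric bitscore '%s'",
          lineno[which(is.na(bitscore))[1]], m[which(is.na(bitscore))[1], 12])
  }
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2], pident = pident,
                   evalue = evalue, bitscore = bitscore,
                   stringsAsFactors = FALSE)
  homology_table(df)
}

#' Construct / validate a HomologyTable
#'
#' Applies best-hit reduction (maximal bitscore per pair) and checks that all
#' stored bitscores are positive.
#'
#' @param df data frame with columns `gene_a`, `gene_b`, `bitscore` and
#'   optionally `pident`, `evalue`.
#' @return a `HomologyTable` data frame.
#' @export
homology_table <- function(df) {
  req <- c("gene_a", "gene_b", "bitscore")
  if (!all(req %in% names(df))) {
    stopf("homology table needs columns %s", paste(req, collapse = ", "))
  }
  if (!"pident" %in% names(df)) df$pident <- NA_real_
  if (!"evalue" %in% names(df)) df$evalue <- NA_real_
  df <- df[, c("gene_a", "gene_b", "pident", "evalue", "bitscore")]
  if (nrow(df)) {
    if (any(df$bitscore <= 0)) stopf("bitscore must be positive for every record")
    key <- paste(df$gene_a, df$gene_b, sep = "\r")
    ord <- order(key, -df$bitscore)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("HomologyTable", "data.frame")
  df
}

#' Write a HomologyTable as BLAST outfmt 6
#'
#' Columns other than pident/evalue/bitscore are filled with neutral
#' placeholder alignment coordinates.
#'
#' @param ht a `HomologyTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast6 <- function(ht, path) {
  n <- nrow(ht)
  lines <- character(n)
  if (n) {
    pident <- ifelse(is.na(ht$pident), 100, ht$pident)
    evalue <- ifelse(is.na(ht$evalue), 0, ht$evalue)
    lines <- sprintf("%s\t%s\t%.1f\t100\t0\t0\t1\t100\t1\t100\t%.3g\t%.6g",
                     ht$gene_a, ht$gene_b, pident, evalue, ht$bitscore)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Inverse BLAST score of a gene pair
#'
#' The reciprocal of the pair's best-hit bitscore; pairs with no homology
#' record get `Inf`, encoding "no detectable sequence similarity", which
#' passes the strict `> 0.010` analog filter.
#'
#' @param gene_a,gene_b vectors of gene ids (recycled to common length).
#' @param homology a `HomologyTable` after best-hit reduction.
#' @return numeric vector of inverse bitscores in `(0, Inf]`.
#' @export
inverse_blast <- function(gene_a, gene_b, homology) {
  n <- max(length(gene_a), length(gene_b))
  gene_a <- rep_len(gene_a, n); gene_b <- rep_len(gene_b, n)
  key <- paste(gene_a, gene_b, sep = "\r")
  hkey <- paste(homology$gene_a, homology$gene_b, sep = "\r")
  idx <- match(key, hkey)
  out <- rep(Inf, n)
  hit <- !is.na(idx)
  out[hit] <- 1 / homology$bitscore[idx[hit]]
  out
}

#' Build a bitscore-weighted gene translation map
#'
#' For every source gene the outgoing weights over its homology hits are
#' proportional to bitscore and normalised to sum to one; genes without hits
#' have no translation. Both directions are built.
#'
#' @param homology a `HomologyTable` after best-hit reduction.
#' @param genes_a,genes_b the full gene universes of the two species; rows of
#'   the returned matrices.
#' @return a list with sparse matrices `ab` (genes_a x genes_b, rows sum to 1
#'   where any hit exists) and `ba` (genes_b x genes_a).
#' @export
build_gene_translation <- function(homology, genes_a, genes_b) {
  ia <- match(homology$gene_a, genes_a)
  ib <- match(homology$gene_b, genes_b)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]; w <- homology$bitscore[ok]
  mk <- function(i, j, w, nr, nc, rn, cn) {
    m <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(nr, nc),
                              dimnames = list(rn, cn))
    rs <- Matrix::rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
    m
  }
  list(
    ab = mk(ia, ib, w, length(genes_a), length(genes_b), genes_a, genes_b),
    ba = mk(ib, ia, w, length(genes_b), length(genes_a), genes_b, genes_a)
  )
}
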