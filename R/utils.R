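#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix readMM writeMM t colSums rowSums sparseMatrix Diagonal
#' @importFrom stats prcomp rnbinom rlnorm runif rnorm cor p.adjust pnorm
#'   setNames quantile sd var median plogis
#' @importFrom utils write.table read.delim head modifyList
NULL

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

.am_env <- new.env(parent = emptyenv())
.am_env$log_level <- "info"

#' Set the package log level
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level) {
  level <- match.arg(level, names(.log_levels))
  old <- .am_env$log_level
  .am_env$log_level <- level
  invisible(old)
}

am_log <- function(level, fmt, ...) {
  if (.log_levels[[level]] >= .log_levels[[.am_env$log_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Write a data frame as a TSV file
#'
#' UTF-8, tab-delimited, header row, no quoting; numeric columns are printed
#' with 6 significant digits so repeated runs are byte-comparable.
#'
#' @param df a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.finite(out[[j]]) | is.na(out[[j]]),
                         formatC(out[[j]], format = "g", digits = 6),
                         ifelse(out[[j]] > 0, "inf", "-inf"))
      out[[j]][is.na(df[[j]])] <- "NA"
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

# deterministic seed derivation for pipeline stages; keeps values < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
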