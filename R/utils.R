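`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Write sequences to a FASTA file
#'
#' @param x named character vector of sequences, or a character matrix with
#'   one row per sequence (row names used as identifiers).
#' @param path output file path.
#' @param width line width for wrapping sequence text.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.matrix(x)) x <- setNames(apply(x, 1L, paste0, collapse = ""), rownames(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop2("write_fasta(): all sequences must be named")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Deterministic TSV writer (no quoting, no row names).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE, ...)
}

# Fixed-format scientific notation for E-values: parses back to the same
# double, keeps outputs byte-stable across runs.
format_evalue <- function(e) sprintf("%.6e", e)

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
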