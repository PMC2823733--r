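# Ingestion of tabular homology-search output (BLAST outfmt-6 dialect),
# normalization, taxonomy annotation and per-query grouping.

HIT_COLS_12 <- c("query_id", "subject_id", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a tabular homology hit file (outfmt-6 dialect)
#'
#' Accepts the standard 12-column tab-separated format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) or a 13-column variant with a trailing subject length
#' (`slen`). Blank lines and `#` comments are skipped. `0.0` E-values are
#' stored as exact zero. Malformed rows fail with their line number.
#'
#' @param path path to the TSV file, or `NULL` when `text` is given.
#' @param dialect `"auto"` (detect from the first data row), `"12col"` or
#'   `"13col"`.
#' @param text optional literal table text instead of a file.
#' @return a data frame of class `hit_table`; `subject_length` is `NA` for
#'   12-column input.
#' @export
read_hit_table <- function(path = NULL, dialect = c("auto", "12col", "13col"),
                           text = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) {
    out <- data.frame(matrix(nrow = 0, ncol = 13))
    names(out) <- c(HIT_COLS_12, "subject_length")
    class(out) <- c("hit_table", "data.frame")
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  want <- switch(dialect, "12col" = 12L, "13col" = 13L,
                 auto = ncols[[1L]])
  if (!want %in% c(12L, 13L))
    stop2("read_hit_table(): line ", keep[1L], ": expected 12 or 13 columns, got ",
          want)
  bad <- which(ncols != want)
  if (length(bad))
    stop2("read_hit_table(): line ", keep[bad[1L]], ": expected ", want,
          " columns, got ", ncols[bad[1L]])
  m <- do.call(rbind, fields)
  num <- function(j, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop2("read_hit_table(): line ", keep[which(is.na(v))[1L]],
            ": non-numeric ", what, " '", m[which(is.na(v))[1L], j], "'")
    if (integer) as.integer(round(v)) else v
  }
  out <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pident = num(3L, "percent identity"),
    length = num(4L, "alignment length", TRUE),
    mismatch = num(5L, "mismatch count", TRUE),
    gapopen = num(6L, "gapopen count", TRUE),
    qstart = num(7L, "qstart", TRUE), qend = num(8L, "qend", TRUE),
    sstart = num(9L, "sstart", TRUE), send = num(10L, "send", TRUE),
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
    subject_length = if (want == 13L) num(13L, "subject length", TRUE)
                     else NA_integer_,
    stringsAsFactors = FALSE)
  if (any(out$evalue < 0))
    stop2("read_hit_table(): negative E-value at line ",
          keep[which(out$evalue < 0)[1L]])
  if (any(out$qstart > out$qend) || any(out$sstart > out$send))
    stop2("read_hit_table(): start > end coordinates at line ",
          keep[which(out$qstart > out$qend | out$sstart > out$send)[1L]])
  if (any(out$length < 1L))
    stop2("read_hit_table(): alignment length < 1 at line ",
          keep[which(out$length < 1L)[1L]])
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Attach taxonomy and clade labels to hits, grouped and sorted per query
#'
#' Each hit gains the subject's taxon id and the names of all defined clades
#' containing that taxon. Hits are grouped by query and sorted by E-value
#' ascending, then bitscore descending, then subject id (a total order: the
#' CSP rules walk hits from strongest to weakest). Self-hits (subject id equal
#' to the query id) are removed.
#'
#' @param hits a `hit_table` from [read_hit_table()].
#' @param map a [taxonomy_map()].
#' @param defs optional [clade_defs()]; when given, a `clades` column
#'   (comma-separated clade names) is added.
#' @param unknown_policy `"strict"` errors on subject ids absent from the map;
#'   `"foreign"` labels them with taxon `"unknown_foreign"`.
#' @return a data frame of class `annotated_hits` with added `taxon_id`,
#'   `query_taxon` and (optionally) `clades` columns.
#' @export
annotate_hits <- function(hits, map, defs = NULL,
                          unknown_policy = c("strict", "foreign")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(map, "taxonomy_map"))
  h <- as.data.frame(hits, stringsAsFactors = FALSE)
  h <- h[h$subject_id != h$query_id, , drop = FALSE]   # self-hit removal
  tax <- unname(map$seq2taxon[h$subject_id])
  if (anyNA(tax)) {
    missing_ids <- sort(unique(h$subject_id[is.na(tax)]))
    if (unknown_policy == "strict")
      stop2("annotate_hits(): subject ids not in taxonomy map: ",
            paste(missing_ids, collapse = ", "))
    tax[is.na(tax)] <- "unknown_foreign"
  }
  h$taxon_id <- tax
  h$query_taxon <- unname(map$seq2taxon[h$query_id])
  if (!is.null(defs)) {
    stopifnot(inherits(defs, "clade_defs"))
    memb <- lapply(names(defs$sets), function(nm) h$taxon_id %in% defs$sets[[nm]])
    lab <- rep("", nrow(h))
    for (i in seq_along(memb))
      lab <- ifelse(memb[[i]], paste(lab, names(defs$sets)[i], sep = ","), lab)
    h$clades <- sub("^,", "", lab)
  }
  h <- h[order(h$query_id, h$evalue, -h$bitscore, h$subject_id,
               method = "radix"), , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "taxonomy_map") <- map
  class(h) <- c("annotated_hits", "data.frame")
  h
}

#' Write annotated hits as TSV
#'
#' Normalized hits with the added `taxon_id` and `clades` columns.
#'
#' @param hits an `annotated_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated_hits <- function(hits, path) {
  h <- as.data.frame(hits)
  h$evalue <- format_evalue(h$evalue)
  attr(h, "taxonomy_map") <- NULL
  write_tsv(h, path)
}

# Split annotated hits into a per-query list (preserving sort order).
hits_by_query <- function(hits) {
  split(as.data.frame(hits), factor(hits$query_id, levels = unique(hits$query_id)))
}
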