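# Conserved signature indel (CSI) detection in protein alignments.
#
# A CSI is a contiguous alignment region where gap state separates a clade
# from everything else (clade holds residues where all others are gapped, or
# vice versa), bordered on both sides by conserved, gap-free flanks that
# anchor the homology of the region. Outgroup state polarizes the indel as an
# insertion or a deletion in the clade.

#' Read a protein multiple sequence alignment from FASTA
#'
#' Sequences must be equal length over the 20 amino-acid letters plus `-`;
#' lowercase is normalized to uppercase and `.` gaps are rejected (inputs must
#' be full-letter FASTA, not dash-notation renderings).
#'
#' @param path FASTA file path, or `NULL` when `text` is given.
#' @param text optional literal FASTA text.
#' @return a character matrix of class `msa` (rows = sequences, row names =
#'   identifiers, columns = alignment columns).
#' @export
read_alignment <- function(path = NULL, text = NULL) {
  if (is.null(path)) {
    stopifnot(!is.null(text))
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(text, path)
  }
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop2("read_alignment(): no sequences in ", path)
  ids <- sub("[ \t].*$", "", names(set))
  seqs <- toupper(as.character(set))
  as_msa(setNames(seqs, ids))
}

#' Build an `msa` object from named sequences
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return a character matrix of class `msa`.
#' @export
as_msa <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop2("as_msa(): sequences must be named")
    if (anyDuplicated(names(seqs)))
      stop2("as_msa(): duplicate sequence ids: ",
            paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
    w <- nchar(seqs)
    if (length(unique(w)) != 1L) {
      short <- names(seqs)[which.min(w)]
      stop2("as_msa(): unequal sequence lengths (e.g. '", short, "' has ",
            min(w), " columns, expected ", max(w), ")")
    }
    m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
    rownames(m) <- names(seqs)
  }
  bad <- setdiff(unique(as.vector(m)), c(AA_LETTERS, "-"))
  if (length(bad))
    stop2("as_msa(): illegal alignment characters: ",
          paste(sQuote(bad), collapse = ", "),
          if ("." %in% bad) " ('.' gaps are not accepted; use '-')" else "")
  class(m) <- c("msa", class(m))
  m
}

msa_strings <- function(msa) apply(unclass(msa), 1L, paste0, collapse = "")

#' Parameters of the CSI scanner
#'
#' @param flank_width number of conserved columns required on each side of a
#'   candidate region (default 5).
#' @param flank_min_identity minimum per-column fraction of sequences matching
#'   the column's majority residue within the flanks (default 0.6).
#' @param flank_gap_free require flank columns to be gap-free in every
#'   sequence (default `TRUE`).
#' @param tolerance maximum fraction of sequences per side (clade /
#'   non-clade) allowed to violate the gap pattern in a region column
#'   (default 0: strict separation).
#' @param min_length minimum region width in columns (default 1).
#' @return an object of class `csi_params`.
#' @export
csi_params <- function(flank_width = 5L, flank_min_identity = 0.6,
                       flank_gap_free = TRUE, tolerance = 0,
                       min_length = 1L) {
  stopifnot(flank_width >= 1, flank_min_identity > 0, flank_min_identity <= 1,
            is.logical(flank_gap_free), tolerance >= 0, tolerance < 0.5,
            min_length >= 1)
  structure(list(flank_width = as.integer(flank_width),
                 flank_min_identity = flank_min_identity,
                 flank_gap_free = isTRUE(flank_gap_free),
                 tolerance = tolerance, min_length = as.integer(min_length)),
            class = "csi_params")
}

# fraction of sequences matching the modal residue, per column (gaps never
# count as the majority residue but do count in the denominator)
column_majority_fraction <- function(m) {
  apply(m, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(0)
    max(table(res)) / length(col)
  })
}

#' Scan an alignment for clade-diagnostic indels
#'
#' Finds maximal contiguous column runs of width at least `min_length` where
#' at least `1 - tolerance` of clade members hold residues while at least
#' `1 - tolerance` of all non-clade sequences are gapped (pattern A), or the
#' reverse (pattern B). Both flanks of width `flank_width` must be gap-free
#' (when required) and conserved (per-column majority fraction at or above
#' `flank_min_identity`). With outgroup sequences designated, pattern A
#' regions where the outgroup is gapped are polarized as insertions in the
#' clade, and pattern B regions where the outgroup holds residues as
#' deletions in the clade. Indel lengths are residue counts on the
#' residue-holding side (clade for insertions, non-clade for deletions), not
#' column counts. Coordinates are 0-based, half-open.
#'
#' @param msa an [as_msa()] matrix.
#' @param clade_members sequence ids of the candidate clade.
#' @param outgroup sequence ids of designated outgroups (disjoint from
#'   `clade_members`); may be empty, in which case polarity is `NA`.
#' @param params a [csi_params()] object.
#' @param aln_id identifier recorded on each call.
#' @return a data frame of class `csi_calls` with columns `aln_id`, `start`,
#'   `end` (0-based half-open), `len_min`, `len_max`, `polarity`
#'   (`insert_in_clade` / `deletion_in_clade` / `NA`), `pattern`,
#'   `flank_left`, `flank_right` (mean majority fractions), `supporting`,
#'   `violating` (comma-separated clade member ids).
#' @export
scan_indels <- function(msa, clade_members, outgroup = character(0),
                        params = csi_params(), aln_id = "aln") {
  stopifnot(inherits(msa, "msa"))
  ids <- rownames(msa)
  clade_members <- unique(as.character(clade_members))
  outgroup <- unique(as.character(outgroup))
  unknown <- setdiff(c(clade_members, outgroup), ids)
  if (length(unknown))
    stop2("scan_indels(): ids not in alignment: ", paste(unknown, collapse = ", "))
  if (length(intersect(clade_members, outgroup)))
    stop2("scan_indels(): clade and outgroup sets overlap: ",
          paste(intersect(clade_members, outgroup), collapse = ", "))
  nonclade <- setdiff(ids, clade_members)
  if (!length(clade_members)) stop2("scan_indels(): empty clade set")
  if (!length(nonclade)) stop2("scan_indels(): non-clade set is empty")

  m <- unclass(msa)
  gap <- m == "-"
  cl <- ids %in% clade_members
  nc <- !cl
  frac_clade_res <- colMeans(!gap[cl, , drop = FALSE])
  frac_non_gap <- colMeans(gap[nc, , drop = FALSE])
  frac_clade_gap <- 1 - frac_clade_res
  frac_non_res <- 1 - frac_non_gap
  thr <- 1 - params$tolerance
  colA <- frac_clade_res >= thr & frac_non_gap >= thr
  colB <- frac_clade_gap >= thr & frac_non_res >= thr

  # majority fractions computed lazily: only candidate flank columns need them
  ncol_m <- ncol(m)
  maj_vals <- rep(NA_real_, ncol_m)
  get_maj <- function(cols) {
    miss <- cols[is.na(maj_vals[cols])]
    if (length(miss))
      maj_vals[miss] <<- column_majority_fraction(m[, miss, drop = FALSE])
    maj_vals[cols]
  }

  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= params$min_length
    data.frame(start = starts[keep], end = ends[keep])  # 1-based inclusive
  }

  flank_ok <- function(s, e) {
    F <- params$flank_width
    ls <- s - F; re <- e + F
    if (ls < 1L || re > ncol_m) return(NULL)
    lcols <- ls:(s - 1L); rcols <- (e + 1L):re
    if (params$flank_gap_free &&
        (any(gap[, lcols]) || any(gap[, rcols]))) return(NULL)
    lm <- get_maj(lcols); rm_ <- get_maj(rcols)
    if (any(lm < params$flank_min_identity) ||
        any(rm_ < params$flank_min_identity)) return(NULL)
    c(mean(lm), mean(rm_))
  }

  calls <- list()
  for (pattern in c("A", "B")) {
    runs <- runs_of(if (pattern == "A") colA else colB)
    for (k in seq_len(nrow(runs))) {
      s <- runs$start[k]; e <- runs$end[k]
      fl <- flank_ok(s, e)
      if (is.null(fl)) next
      region <- m[, s:e, drop = FALSE]
      res_counts <- rowSums(region != "-")
      if (pattern == "A") {
        supporting <- clade_members[res_counts[match(clade_members, ids)] > 0]
        carriers <- supporting
      } else {
        supporting <- clade_members[res_counts[match(clade_members, ids)] <
                                      (e - s + 1L)]
        carriers <- nonclade[res_counts[match(nonclade, ids)] > 0]
      }
      violating <- setdiff(clade_members, supporting)
      if (!length(carriers)) next
      lens <- res_counts[match(carriers, ids)]
      polarity <- NA_character_
      if (length(outgroup)) {
        og_cells <- m[match(outgroup, ids), s:e, drop = FALSE]
        if (pattern == "A" && all(og_cells == "-")) polarity <- "insert_in_clade"
        if (pattern == "B" && all(og_cells != "-")) polarity <- "deletion_in_clade"
      }
      calls[[length(calls) + 1L]] <- data.frame(
        aln_id = aln_id, start = s - 1L, end = e,       # 0-based half-open
        len_min = as.integer(min(lens)), len_max = as.integer(max(lens)),
        polarity = polarity, pattern = pattern,
        flank_left = fl[1], flank_right = fl[2],
        supporting = paste(sort(supporting), collapse = ","),
        violating = paste(sort(violating), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(aln_id = character(0), start = integer(0), end = integer(0),
               len_min = integer(0), len_max = integer(0),
               polarity = character(0), pattern = character(0),
               flank_left = numeric(0), flank_right = numeric(0),
               supporting = character(0), violating = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("csi_calls", "data.frame")
  out
}

#' Write CSI calls as TSV
#'
#' Columns: `aln_id start end len_min len_max polarity clade` plus flank and
#' support bookkeeping. Coordinates 0-based half-open.
#'
#' @param calls a `csi_calls` data frame (a `clade` column is added when the
#'   calls carry one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csi_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls), path)
}

#' Render a CSI call in dash notation
#'
#' Text rendering of the call's region plus `flank` columns on each side, in
#' the publication convention: the first sequence is printed in full and
#' every other sequence shows a letter only where it differs (a dash `-`
#' marks identity with the top sequence; alignment gaps print as blanks would
#' be ambiguous, so gaps keep `-` in the top row and `.` elsewhere).
#'
#' @param msa the alignment the call was made on.
#' @param call one row of a `csi_calls` data frame.
#' @param flank columns of context on each side (default the scanner's 5).
#' @param reference id of the sequence to print in full (default: first row).
#' @return character vector of rendered lines.
#' @export
render_indel <- function(msa, call, flank = 5L, reference = NULL) {
  m <- unclass(msa)
  s <- max(1L, call$start + 1L - flank)
  e <- min(ncol(m), call$end + flank)
  ref <- reference %||% rownames(m)[1L]
  ri <- match(ref, rownames(m))
  if (is.na(ri)) stop2("render_indel(): no sequence '", ref, "'")
  block <- m[, s:e, drop = FALSE]
  top <- block[ri, ]
  lines <- vapply(seq_len(nrow(block)), function(i) {
    if (i == ri) return(paste0(top, collapse = ""))
    row <- block[i, ]
    shown <- ifelse(row == top & row != "-", "-",
                    ifelse(row == "-", ".", row))
    paste0(shown, collapse = "")
  }, "")
  paste0(format(rownames(block), width = max(nchar(rownames(block)))), "  ",
         lines)
}
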