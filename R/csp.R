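# Clade-specific signature protein (CSP) calling.
#
# A protein is specific for a target clade expression when its homologs are
# (essentially) confined to that clade: every significant hit comes from the
# target taxa, or the E-values jump by orders of magnitude between the last
# in-clade hit and the first foreign hit, with the foreign E-values above the
# significance ceiling (weak similarity attributable to chance). Proteins seen
# in only one taxon (ORFans) are excluded; homologs tolerated in whitelisted
# groups (plants/plastids) or in a single isolated foreign taxon are retained
# with an exception note.

#' Parameters of the CSP decision procedure
#'
#' @param e_sig significance ceiling for foreign hits: a foreign hit with
#'   E-value at or below this disqualifies (default `1e-4`, the classical
#'   "could occur by chance" boundary).
#' @param e_presence maximum E-value for counting a target-clade member as
#'   possessing a homolog (default `1e-6`, stricter than `e_sig`).
#' @param gap_factor minimum ratio of the first foreign E-value to the last
#'   in-clade presence E-value for the "large increase in E values" evidence
#'   (default `1e3`); recorded as supporting evidence on each decision.
#' @param length_ratio_bounds allowed subject/query length ratio interval for
#'   a hit to establish presence, applied when the subject length is known
#'   (default `c(0.7, 1.3)`).
#' @param min_members minimum number of target taxa with a homolog; below this
#'   the protein is an ORFan-like singleton and is excluded (default 2).
#' @param max_missing maximum number of target taxa allowed to lack a homolog
#'   for the "missing in 1-2 isolated species/strains" tier (default 2).
#' @param exception_groups group tags whose taxa never disqualify a call
#'   (default `"plastid_eukaryote"`).
#' @param max_isolated_foreign maximum number of distinct non-whitelisted
#'   foreign taxa with significant hits that still yields a retained call with
#'   an exception note (default 1).
#' @param e_floor floor applied to E-values inside ratio computations only
#'   (default `1e-180`); stored E-values are never mutated.
#' @param length_check `"hard"` (default) makes the length ratio a presence
#'   filter; `"warn"` only annotates violations.
#' @return an object of class `csp_params`.
#' @export
csp_params <- function(e_sig = 1e-4, e_presence = 1e-6, gap_factor = 1e3,
                       length_ratio_bounds = c(0.7, 1.3), min_members = 2L,
                       max_missing = 2L,
                       exception_groups = "plastid_eukaryote",
                       max_isolated_foreign = 1L, e_floor = 1e-180,
                       length_check = c("hard", "warn")) {
  length_check <- match.arg(length_check)
  stopifnot(e_presence > 0, e_presence <= e_sig, e_sig < 1,
            gap_factor > 1, min_members >= 2,
            length(length_ratio_bounds) == 2,
            length_ratio_bounds[1] < 1, length_ratio_bounds[2] > 1,
            max_missing >= 0, max_isolated_foreign >= 0, e_floor > 0)
  structure(list(e_sig = e_sig, e_presence = e_presence,
                 gap_factor = gap_factor,
                 length_ratio_bounds = length_ratio_bounds,
                 min_members = as.integer(min_members),
                 max_missing = as.integer(max_missing),
                 exception_groups = as.character(exception_groups),
                 max_isolated_foreign = as.integer(max_isolated_foreign),
                 e_floor = e_floor, length_check = length_check),
            class = "csp_params")
}

#' Read CSP parameters from a flat key=value config file
#'
#' Unknown keys are an error; missing keys take their defaults. Vector values
#' (length bounds, exception groups) are comma-separated.
#'
#' @param path config file path.
#' @return a [csp_params()] object.
#' @export
read_csp_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop2("read_csp_config(): malformed line: ",
          lines[which(lengths(kv) != 2L)[1L]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      e_sig = , e_presence = , gap_factor = , e_floor = as.numeric(v),
      min_members = , max_missing = , max_isolated_foreign = as.integer(v),
      length_ratio_bounds = as.numeric(strsplit(v, ",")[[1]]),
      exception_groups = strsplit(v, ",")[[1]],
      length_check = v,
      stop2("read_csp_config(): unknown key '", k, "'"))
  }
  do.call(csp_params, args)
}

#' Classify one protein against one clade expression
#'
#' Decision procedure:
#' \enumerate{
#'   \item Presence set P: target taxa with at least one hit at
#'     `E <= e_presence` whose subject length (when known) is within
#'     `length_ratio_bounds` of the query length. The query's own taxon counts
#'     as present when it belongs to the target (its self-hit was removed on
#'     ingestion).
#'   \item `|P| < min_members` is an ORFan-like singleton: `orfan_excluded`.
#'   \item Foreign hits are hits to taxa outside the resolved target;
#'     whitelisted taxa (group tags intersecting `exception_groups`) are set
#'     aside and never disqualify.
#'   \item No significant foreign hit (all foreign E-values above `e_sig`)
#'     keeps the protein specific; the ratio of the first foreign E-value to
#'     the last in-clade presence E-value is recorded, with a note when it
#'     falls below `gap_factor`.
#'   \item Significant foreign hits from at most `max_isolated_foreign`
#'     distinct taxa (or from whitelisted taxa only) downgrade the call to
#'     `retained_with_exception`; more foreign taxa reject it.
#'   \item Completeness: `specific_core` when P covers the whole target,
#'     `specific_partial` when 1..`max_missing` members are missing, otherwise
#'     `not_specific`.
#' }
#'
#' @param query_id query protein identifier.
#' @param query_length query protein length (aa).
#' @param hits the query's rows of an [annotate_hits()] table (may be empty).
#' @param target a clade expression (string or [clade()] object).
#' @param defs a [clade_defs()] object.
#' @param params a [csp_params()] object.
#' @param map optional [taxonomy_map()] used to look up group tags and the
#'   query's taxon; defaults to the map attached by [annotate_hits()].
#' @param query_taxon the query's taxon id; defaults to a map lookup.
#' @return an object of class `csp_decision` with fields `query_id`, `target`,
#'   `verdict`, `presence_taxa`, `missing_taxa`, `foreign_evidence` (data
#'   frame of taxon/evalue), `gap_ratio` and `notes`.
#' @export
classify_protein <- function(query_id, query_length, hits, target, defs,
                             params = csp_params(), map = NULL,
                             query_taxon = NULL) {
  stopifnot(inherits(params, "csp_params"))
  map <- map %||% attr(hits, "taxonomy_map")
  target <- as_clade_expr(target)
  tset <- resolve_clade(target, defs)
  h <- as.data.frame(hits)
  if (nrow(h)) h <- h[h$subject_id != query_id, , drop = FALSE]
  if (is.null(query_taxon) && !is.null(map))
    query_taxon <- unname(map$seq2taxon[query_id])

  decision <- function(verdict, presence, missing, foreign_ev, gap_ratio,
                       notes) {
    structure(list(query_id = query_id, target = format(target),
                   verdict = verdict,
                   presence_taxa = sort(presence),
                   missing_taxa = sort(missing),
                   foreign_evidence = foreign_ev, gap_ratio = gap_ratio,
                   notes = notes),
              class = "csp_decision")
  }

  notes <- character(0)

  # (1) presence
  in_target <- if (nrow(h)) h$taxon_id %in% tset else logical(0)
  qualifies <- if (nrow(h)) h$evalue <= params$e_presence else logical(0)
  if (nrow(h)) {
    known_len <- !is.na(h$subject_length)
    ratio_ok <- rep(TRUE, nrow(h))
    ratio_ok[known_len] <-
      h$subject_length[known_len] >= params$length_ratio_bounds[1] * query_length &
      h$subject_length[known_len] <= params$length_ratio_bounds[2] * query_length
    if (params$length_check == "hard") {
      qualifies <- qualifies & ratio_ok
    } else if (any(in_target & qualifies & !ratio_ok)) {
      notes <- c(notes, "length_ratio_violations_ignored")
    }
  }
  presence <- unique(h$taxon_id[in_target & qualifies])
  if (!is.null(query_taxon) && !is.na(query_taxon) && query_taxon %in% tset)
    presence <- union(presence, query_taxon)
  presence_e <- if (length(presence)) {
    vapply(presence, function(tx) {
      e <- h$evalue[in_target & qualifies & h$taxon_id == tx]
      if (length(e)) min(e) else 0   # own taxon: presence by identity
    }, 0)
  } else numeric(0)

  # (2) ORFan exclusion
  if (length(presence) < params$min_members)
    return(decision("orfan_excluded", presence, setdiff(tset, presence),
                    data.frame(taxon = character(0), evalue = numeric(0)),
                    NA_real_, "fewer target taxa with homologs than min_members"))

  # (3) foreign hits; whitelisted taxa set aside
  foreign <- h[!(h$taxon_id %in% tset), , drop = FALSE]
  whitelisted_taxon <- vapply(foreign$taxon_id, function(tx) {
    tags <- if (!is.null(map)) taxon_tags(map, tx) else character(0)
    length(intersect(tags, params$exception_groups)) > 0
  }, TRUE)
  white <- foreign[whitelisted_taxon, , drop = FALSE]
  foreign <- foreign[!whitelisted_taxon, , drop = FALSE]

  sig_foreign <- foreign[foreign$evalue <= params$e_sig, , drop = FALSE]
  sig_taxa <- unique(sig_foreign$taxon_id)
  foreign_ev <- if (nrow(foreign)) {
    agg <- tapply(foreign$evalue, foreign$taxon_id, min)
    data.frame(taxon = names(agg), evalue = unname(agg),
               stringsAsFactors = FALSE)
  } else data.frame(taxon = character(0), evalue = numeric(0))
  foreign_ev <- foreign_ev[order(foreign_ev$evalue, foreign_ev$taxon), ,
                           drop = FALSE]
  rownames(foreign_ev) <- NULL

  gap_ratio <- if (nrow(foreign)) {
    last_in <- max(presence_e, params$e_floor)
    max(min(foreign$evalue), params$e_floor) / last_in
  } else NA_real_

  # (6) completeness (evaluated here, applied below)
  missing <- setdiff(tset, presence)
  completeness <- if (!length(missing)) "core"
                  else if (length(missing) <= params$max_missing) "partial"
                  else "fail"
  if (completeness == "fail")
    return(decision("not_specific", presence, missing, foreign_ev, gap_ratio,
                    paste0("missing in ", length(missing),
                           " target taxa (> max_missing)")))

  white_sig_taxa <- unique(white$taxon_id[white$evalue <= params$e_sig])

  # (4) / (5) foreign significance
  if (length(sig_taxa) == 0) {
    if (!is.na(gap_ratio) && gap_ratio < params$gap_factor)
      notes <- c(notes, sprintf("gap_ratio %.3g below gap_factor %.3g",
                                gap_ratio, params$gap_factor))
    if (length(white_sig_taxa))
      return(decision("retained_with_exception", presence, missing, foreign_ev,
                      gap_ratio,
                      c(notes, paste0("whitelisted group hit: ",
                                      paste(white_sig_taxa, collapse = ",")))))
    verdict <- if (completeness == "core") "specific_core" else "specific_partial"
    if (completeness == "partial")
      notes <- c(notes, paste0("missing in ", length(missing),
                               " isolated target taxa"))
    return(decision(verdict, presence, missing, foreign_ev, gap_ratio, notes))
  }
  if (length(sig_taxa) <= params$max_isolated_foreign)
    return(decision("retained_with_exception", presence, missing, foreign_ev,
                    gap_ratio,
                    c(notes, paste0("significant hit in isolated foreign taxon: ",
                                    paste(sort(sig_taxa), collapse = ",")))))
  decision("not_specific", presence, missing, foreign_ev, gap_ratio,
           paste0("significant foreign hits in ", length(sig_taxa),
                  " taxa; best: ", sig_foreign$taxon_id[1L], " (E=",
                  format_evalue(min(sig_foreign$evalue)), ")"))
}

#' @export
print.csp_decision <- function(x, ...) {
  cat(sprintf("<csp_decision> %s vs %s: %s (%d present, %d missing)\n",
              x$query_id, x$target, x$verdict,
              length(x$presence_taxa), length(x$missing_taxa)))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

positive_verdicts <- c("specific_core", "specific_partial",
                       "retained_with_exception")

#' Call CSPs for a set of query proteins against an ordered target list
#'
#' Targets are evaluated most-specific-first (smallest resolved taxon set
#' first, ties by listed order); each query is assigned to the first target
#' for which [classify_protein()] returns a positive verdict
#' (`specific_core`, `specific_partial` or `retained_with_exception`).
#' Queries matching no target are omitted.
#'
#' @param queries data frame with columns `query_id` and `length` (aa).
#' @param table an [annotate_hits()] table covering the queries.
#' @param targets list of clade expressions (strings or [clade()] objects).
#' @param defs a [clade_defs()] object.
#' @param params a [csp_params()] object.
#' @param map optional [taxonomy_map()] (defaults to the one attached to
#'   `table`).
#' @return a data frame of class `csp_calls`, sorted by target then query id,
#'   with the full `csp_decision` objects in the `decision` list column.
#' @export
call_genome <- function(queries, table, targets, defs, params = csp_params(),
                        map = NULL) {
  stopifnot(is.data.frame(queries), all(c("query_id", "length") %in% names(queries)))
  if (anyDuplicated(queries$query_id))
    stop2("call_genome(): duplicate query ids: ",
          paste(unique(queries$query_id[duplicated(queries$query_id)]),
                collapse = ", "))
  map <- map %||% attr(table, "taxonomy_map")
  targets <- lapply(targets, as_clade_expr)
  sizes <- vapply(targets, function(t) length(resolve_clade(t, defs)), 0L)
  ord <- order(sizes, seq_along(targets))
  targets <- targets[ord]
  target_names <- vapply(targets, format, "")
  byq <- if (nrow(table)) hits_by_query(table) else list()
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    qid <- queries$query_id[i]
    qh <- byq[[qid]]
    if (is.null(qh)) qh <- as.data.frame(table)[0, , drop = FALSE]
    for (j in seq_along(targets)) {
      dec <- classify_protein(qid, queries$length[i], qh, targets[[j]], defs,
                              params, map = map)
      if (dec$verdict %in% positive_verdicts) {
        rows[[length(rows) + 1L]] <- list(
          query_id = qid, target = target_names[j], verdict = dec$verdict,
          n_present = length(dec$presence_taxa),
          missing_taxa = paste(dec$missing_taxa, collapse = ","),
          exceptions = paste(grep("whitelisted|isolated foreign",
                                  dec$notes, value = TRUE), collapse = "; "),
          length = queries$length[i], decision = list(dec))
        break
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(query_id = character(0), target = character(0),
                      verdict = character(0), n_present = integer(0),
                      missing_taxa = character(0), exceptions = character(0),
                      length = numeric(0), stringsAsFactors = FALSE)
    out$decision <- list()
    class(out) <- c("csp_calls", "data.frame")
    return(out)
  }
  out <- data.frame(
    query_id = vapply(rows, `[[`, "", "query_id"),
    target = vapply(rows, `[[`, "", "target"),
    verdict = vapply(rows, `[[`, "", "verdict"),
    n_present = vapply(rows, `[[`, 0L, "n_present"),
    missing_taxa = vapply(rows, `[[`, "", "missing_taxa"),
    exceptions = vapply(rows, `[[`, "", "exceptions"),
    length = vapply(rows, function(r) as.numeric(r$length), 0),
    stringsAsFactors = FALSE)
  out$decision <- lapply(rows, function(r) r$decision[[1L]])
  out <- out[order(match(out$target, target_names), out$query_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("csp_calls", "data.frame")
  out
}

#' Write CSP calls as TSV (table analog) and JSON evidence report
#'
#' The TSV mirrors the published table layout:
#' `query_id target verdict n_present missing_taxa exceptions length`.
#' The JSON report carries the full evidence for every decision.
#'
#' @param calls a `csp_calls` data frame from [call_genome()].
#' @param path TSV output path.
#' @param json_path optional JSON report path.
#' @return `path`, invisibly.
#' @export
write_csp_calls <- function(calls, path, json_path = NULL) {
  d <- as.data.frame(calls)
  d$decision <- NULL
  write_tsv(d, path)
  if (!is.null(json_path)) {
    report <- lapply(seq_len(nrow(calls)), function(i) {
      dec <- calls$decision[[i]]
      list(query_id = dec$query_id, target = dec$target,
           verdict = dec$verdict,
           presence_taxa = dec$presence_taxa,
           missing_taxa = dec$missing_taxa,
           foreign_evidence = dec$foreign_evidence,
           gap_ratio = dec$gap_ratio, notes = dec$notes)
    })
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}
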