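#' Construct a taxonomy map
#'
#' A taxonomy map links sequence (protein) identifiers to taxa, and taxa to
#' group tags used by exception whitelists (e.g. `"plastid_eukaryote"` for
#' homologs tolerated in plants/plastids).
#'
#' @param seq_id character vector of sequence identifiers (unique, non-empty).
#' @param taxon_id character vector of taxon identifiers, parallel to
#'   `seq_id`.
#' @param group_tags optional character vector (comma-separated tags) or list
#'   of character vectors, parallel to `seq_id`; tags are pooled per taxon.
#' @return an object of class `taxonomy_map` with elements `seq2taxon`
#'   (named character vector) and `taxa` (data frame of `taxon_id` and a list
#'   column `tags`).
#' @export
taxonomy_map <- function(seq_id, taxon_id, group_tags = NULL) {
  seq_id <- as.character(seq_id); taxon_id <- as.character(taxon_id)
  if (length(seq_id) != length(taxon_id))
    stop2("taxonomy_map(): seq_id and taxon_id lengths differ")
  if (any(!nzchar(seq_id)) || anyNA(seq_id))
    stop2("taxonomy_map(): empty sequence identifiers")
  if (anyDuplicated(seq_id))
    stop2("taxonomy_map(): duplicate sequence identifiers: ",
          paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  if (any(!nzchar(taxon_id)) || anyNA(taxon_id))
    stop2("taxonomy_map(): empty taxon identifiers")
  if (is.null(group_tags)) group_tags <- rep("", length(seq_id))
  if (is.character(group_tags))
    group_tags <- strsplit(group_tags, ",", fixed = TRUE)
  group_tags <- lapply(group_tags, function(t) sort(unique(t[nzchar(t)])))
  taxa_ids <- sort(unique(taxon_id))
  taxa <- data.frame(taxon_id = taxa_ids, stringsAsFactors = FALSE)
  taxa$tags <- lapply(taxa_ids, function(tx)
    sort(unique(unlist(group_tags[taxon_id == tx]))))
  structure(list(seq2taxon = setNames(taxon_id, seq_id), taxa = taxa),
            class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat("taxonomy_map:", length(x$seq2taxon), "sequences,",
      nrow(x$taxa), "taxa\n")
  invisible(x)
}

#' Taxa present in a taxonomy map
#' @param map a [taxonomy_map()].
#' @return character vector of taxon ids.
#' @export
map_taxa <- function(map) map$taxa$taxon_id

#' Group tags of a taxon
#' @param map a [taxonomy_map()].
#' @param taxon a taxon id.
#' @return character vector of tags (possibly empty).
#' @export
taxon_tags <- function(map, taxon) {
  i <- match(taxon, map$taxa$taxon_id)
  if (is.na(i)) character(0) else map$taxa$tags[[i]]
}

#' Read / write a taxonomy map as TSV
#'
#' Format: `seq_id<TAB>taxon_id<TAB>group_tags` (third column optional,
#' comma-separated). Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return for the reader, a [taxonomy_map()]; the writer returns `path`
#'   invisibly.
#' @export
read_taxonomy_map <- function(path) {
  d <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                  comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character", fill = TRUE)
  if (ncol(d) < 2L) stop2("taxonomy TSV needs >= 2 columns: ", path)
  tags <- if (ncol(d) >= 3L) d[[3L]] else NULL
  taxonomy_map(d[[1L]], d[[2L]], tags)
}

#' @rdname read_taxonomy_map
#' @param map a [taxonomy_map()] to serialize.
#' @export
write_taxonomy_map <- function(map, path) {
  tag_of <- setNames(
    vapply(map$taxa$tags, paste0, "", collapse = ","), map$taxa$taxon_id)
  d <- data.frame(seq_id = names(map$seq2taxon),
                  taxon_id = unname(map$seq2taxon),
                  group_tags = unname(tag_of[unname(map$seq2taxon)]),
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Named clade definitions
#'
#' Clade definitions are stored flat (explicit taxon sets), not derived from a
#' tree, so clade membership and tree topology can be tested independently.
#' Sets may overlap or nest.
#'
#' @param sets named list of character vectors of taxon ids.
#' @param all_taxa the universe used by the `ALL` atom of clade expressions;
#'   defaults to the union of all sets.
#' @param map optional [taxonomy_map()]; when given, every referenced taxon
#'   must exist in it and `all_taxa` defaults to the map's taxa.
#' @return object of class `clade_defs`.
#' @export
clade_defs <- function(sets, all_taxa = NULL, map = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop2("clade_defs(): sets must be named")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (!is.null(map)) {
    unknown <- setdiff(unique(unlist(sets)), map_taxa(map))
    if (length(unknown))
      stop2("clade_defs(): taxa not in taxonomy map: ",
            paste(unknown, collapse = ", "))
    if (is.null(all_taxa)) all_taxa <- map_taxa(map)
  }
  if (is.null(all_taxa)) all_taxa <- sort(unique(unlist(sets)))
  structure(list(sets = sets, all_taxa = sort(unique(as.character(all_taxa)))),
            class = "clade_defs")
}

#' @export
print.clade_defs <- function(x, ...) {
  cat("clade_defs:", length(x$sets), "clades over",
      length(x$all_taxa), "taxa\n")
  for (nm in names(x$sets))
    cat(sprintf("  %s (%d)\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Read / write clade definitions as TSV
#'
#' Format: `clade_name<TAB>taxon_id`, one row per membership. `#` comments
#' skipped.
#'
#' @param path file path.
#' @param map optional [taxonomy_map()] for referential validation.
#' @return a [clade_defs()] object; the writer returns `path` invisibly.
#' @export
read_clade_definitions <- function(path, map = NULL) {
  d <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                  comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(d) != 2L) stop2("clade TSV must have 2 columns: ", path)
  clade_defs(split(d[[2L]], d[[1L]]), map = map)
}

#' @rdname read_clade_definitions
#' @param defs a [clade_defs()] object to serialize.
#' @export
write_clade_definitions <- function(defs, path) {
  d <- do.call(rbind, lapply(names(defs$sets), function(nm)
    data.frame(clade = nm, taxon = defs$sets[[nm]], stringsAsFactors = FALSE)))
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- clade expressions ------------------------------------------------------

new_clade_expr <- function(op, ...) {
  structure(list(op = op, ...), class = "clade_expr")
}

#' Clade set-algebra expressions
#'
#' Expressions over named clades with operators union (`+`), difference (`-`)
#' and the atom `ALL` (every taxon in the definition set's universe). These
#' express compound specificity targets such as "all cyanobacteria except
#' Clade A" or "Clade B and also *S. elongatus*".
#'
#' @param name a clade name defined in a [clade_defs()] object.
#' @return an object of class `clade_expr`.
#' @examples
#' e <- clade_diff(clade_all(), clade("CladeA"))
#' format(e)
#' @export
clade <- function(name) {
  stopifnot(is_string(name))
  new_clade_expr("name", name = name)
}

#' @rdname clade
#' @export
clade_all <- function() new_clade_expr("all")

#' @rdname clade
#' @param ... clade expressions (or clade names) to unite.
#' @export
clade_union <- function(...) {
  args <- lapply(list(...), as_clade_expr)
  if (length(args) < 2L) stop2("clade_union(): need >= 2 operands")
  Reduce(function(a, b) new_clade_expr("union", lhs = a, rhs = b), args)
}

#' @rdname clade
#' @param x,y clade expressions (or clade names); `clade_diff(x, y)` is the
#'   set difference x \ y.
#' @export
clade_diff <- function(x, y) {
  new_clade_expr("diff", lhs = as_clade_expr(x), rhs = as_clade_expr(y))
}

#' @rdname clade
#' @export
as_clade_expr <- function(x) {
  if (inherits(x, "clade_expr")) return(x)
  if (is_string(x)) return(parse_clade_expr(x))
  stop2("cannot interpret as a clade expression: ", deparse(x))
}

#' Parse a clade expression from text
#'
#' Grammar: `NAME`, `ALL`, and left-associative `expr+expr` (union) and
#' `expr-expr` (difference). Whitespace around operators is ignored; clade
#' names may contain letters, digits, `_` and `.`.
#'
#' @param text expression string, e.g. `"Cyano-CladeA"` or
#'   `"CladeB+Elongatus"`.
#' @return a `clade_expr`.
#' @export
parse_clade_expr <- function(text) {
  stopifnot(is_string(text))
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop2("empty clade expression")
  toks <- regmatches(s, gregexpr("[+-]|[A-Za-z0-9_.]+", s))[[1]]
  if (!identical(paste0(toks, collapse = ""), s))
    stop2("cannot parse clade expression: ", text)
  odd <- toks[seq(1L, length(toks), by = 2L)]
  even <- if (length(toks) >= 2L) toks[seq(2L, length(toks), by = 2L)]
          else character(0)
  if (length(toks) %% 2L == 0L || any(odd %in% c("+", "-")) ||
      !all(even %in% c("+", "-")))
    stop2("malformed clade expression: ", text)
  atom <- function(t) if (t == "ALL") clade_all() else clade(t)
  e <- atom(toks[1L])
  i <- 2L
  while (i < length(toks)) {
    e <- if (toks[i] == "+") new_clade_expr("union", lhs = e, rhs = atom(toks[i + 1L]))
         else new_clade_expr("diff", lhs = e, rhs = atom(toks[i + 1L]))
    i <- i + 2L
  }
  e
}

#' @export
format.clade_expr <- function(x, ...) {
  switch(x$op,
    all = "ALL",
    name = x$name,
    union = paste0(format(x$lhs), "+", format(x$rhs)),
    diff = paste0(format(x$lhs), "-", format(x$rhs)))
}

#' @export
print.clade_expr <- function(x, ...) {
  cat("<clade_expr>", format(x), "\n")
  invisible(x)
}

#' Evaluate a clade expression to a taxon set
#'
#' Union is set union, difference is set subtraction, `ALL` is every taxon in
#' `defs$all_taxa`. An expression that evaluates to the empty set is an error
#' (a specificity target must name at least one taxon).
#'
#' @param expr a `clade_expr` (or a string parsed by [parse_clade_expr()]).
#' @param defs a [clade_defs()] object.
#' @return sorted character vector of taxon ids.
#' @export
resolve_clade <- function(expr, defs) {
  expr <- as_clade_expr(expr)
  stopifnot(inherits(defs, "clade_defs"))
  ev <- function(e) {
    switch(e$op,
      all = defs$all_taxa,
      name = {
        if (!e$name %in% names(defs$sets))
          stop2("undefined clade name: ", e$name)
        defs$sets[[e$name]]
      },
      union = union(ev(e$lhs), ev(e$rhs)),
      diff = setdiff(ev(e$lhs), ev(e$rhs)),
      stop2("unknown clade expression operator: ", e$op))
  }
  out <- sort(unique(ev(expr)))
  if (!length(out))
    stop2("clade expression evaluates to the empty set: ", format(expr))
  out
}
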