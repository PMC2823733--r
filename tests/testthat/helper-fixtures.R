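# Shared fixture builders. Everything is constructed in code; no data files.

# quick hit-table constructor: one row per call, sensible filler columns
hit_row <- function(q, s, evalue, bitscore = 100, slen = NA_integer_,
                    pident = 90, len = 100) {
  data.frame(query_id = q, subject_id = s, pident = pident, length = len,
             mismatch = as.integer(round((1 - pident / 100) * len)),
             gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = evalue, bitscore = bitscore,
             subject_length = as.integer(slen), stringsAsFactors = FALSE)
}

make_hit_table <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("hit_table", "data.frame")
  out
}

# five-taxon target world used by the CSP rule tests:
# target clade T = {T1..T5}; foreign taxa F1, F2; whitelisted plastid taxon PL
rule_world <- function() {
  seqs <- c(paste0("T", 1:5, "|fam"), "F1|fam", "F2|fam", "PL|fam", "q1")
  taxa <- c(paste0("T", 1:5), "F1", "F2", "PL", "T1")
  tags <- c(rep("", 7), "plastid_eukaryote", "")
  map <- taxonomy_map(seqs, taxa, tags)
  defs <- clade_defs(list(TargetClade = paste0("T", 1:5)),
                     all_taxa = map_taxa(map))
  list(map = map, defs = defs)
}

# annotated hits for query "q1" (taxon T1) given per-subject E-values
q1_hits <- function(world, evalues, slen = 300L) {
  tbl <- if (length(evalues)) {
    rows <- lapply(names(evalues), function(sid)
      hit_row("q1", sid, evalues[[sid]], bitscore = -log10(evalues[[sid]]),
              slen = slen))
    do.call(make_hit_table, rows)
  } else make_hit_table(hit_row("x", "y", 1))[0, ]
  annotate_hits(tbl, world$map, defs = world$defs)
}

# exhaustive-minimality oracle for Dollo loss counts: try all subsets of
# absence-only nodes under the gain node, smallest first
bf_dollo <- function(tree, present) {
  gain <- mrca_node(tree, present)
  under <- tips_under(tree, gain)
  absent <- setdiff(under, present)
  if (!length(absent)) return(list(gain = gain, n_losses = 0L))
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2],
                factor(tree$edge[, 1], levels = seq_len(nt + tree$Nnode)))
  nodes <- integer(0)
  stack <- gain
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    for (ch in kids[[n]]) {
      nodes <- c(nodes, ch)
      if (ch > nt) stack <- c(stack, ch)
    }
  }
  cand <- nodes[vapply(nodes, function(n)
    !any(tips_under(tree, n) %in% present), TRUE)]
  for (k in seq_len(length(cand))) {
    for (cmb in asplit(combn(cand, k), 2)) {
      covered <- sort(unique(unlist(lapply(cmb, tips_under, tree = tree))))
      if (identical(covered, sort(absent)))
        return(list(gain = gain, n_losses = k))
    }
  }
  stop("bf_dollo: no valid loss set found")
}

# random rooted binary tree with unique labels and positive branch lengths
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- pmax(tr$edge.length, 1e-3)
  tr
}

# random gapless alignment
random_alignment <- function(n_seq, n_col) {
  m <- matrix(sample(cladesig:::AA_LETTERS, n_seq * n_col, replace = TRUE),
              nrow = n_seq)
  rownames(m) <- paste0("s", seq_len(n_seq))
  as_msa(m)
}
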