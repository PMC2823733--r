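# Dollo parsimony on presence/absence: each protein family is gained exactly
# once (at the MRCA of the taxa possessing it) and thereafter only lost; the
# losses are the maximal absent subtrees under the gain node, which is the
# minimum number of loss events compatible with a single origin.

#' Build a presence/absence matrix
#'
#' Rows are protein families, columns taxa, entries 0/1. Input is either a
#' `csp_calls` data frame (presence sets of the underlying decisions) or an
#' [annotate_hits()] table (a taxon is present for a query when it has a hit
#' at `E <= e_presence`). All-zero rows are dropped with a warning.
#'
#' @param x a `csp_calls` data frame or an `annotated_hits` data frame.
#' @param taxa character vector of taxon ids; must equal the leaf set of the
#'   reference tree the matrix will be mapped onto.
#' @param e_presence presence threshold, used for hit-table input.
#' @param family_of optional function mapping a query id to its family id
#'   (default: identity — one row per query).
#' @return a 0/1 integer matrix with family row names and taxon column names.
#' @export
build_presence_matrix <- function(x, taxa, e_presence = 1e-6,
                                  family_of = identity) {
  taxa <- sort(unique(as.character(taxa)))
  sets <- list()
  if (inherits(x, "csp_calls")) {
    for (i in seq_len(nrow(x))) {
      fam <- family_of(x$query_id[i])
      sets[[fam]] <- union(sets[[fam]], x$decision[[i]]$presence_taxa)
    }
  } else if (inherits(x, "annotated_hits") || is.data.frame(x)) {
    h <- as.data.frame(x)
    need <- c("query_id", "taxon_id", "evalue")
    if (!all(need %in% names(h)))
      stop2("build_presence_matrix(): need columns ",
            paste(need, collapse = ", "))
    h <- h[h$evalue <= e_presence, , drop = FALSE]
    for (q in unique(h$query_id)) {
      fam <- family_of(q)
      sets[[fam]] <- union(sets[[fam]],
                           h$taxon_id[h$query_id == q])
    }
  } else stop2("build_presence_matrix(): unsupported input")
  if (!length(sets))
    return(matrix(integer(0), nrow = 0, ncol = length(taxa),
                  dimnames = list(NULL, taxa)))
  unknown <- setdiff(unique(unlist(sets)), taxa)
  if (length(unknown))
    stop2("build_presence_matrix(): taxa absent from the reference leaf set: ",
          paste(unknown, collapse = ", "))
  m <- t(vapply(sets, function(s) as.integer(taxa %in% s),
                integer(length(taxa))))
  colnames(m) <- taxa
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero presence rows")
    m <- m[!zero, , drop = FALSE]
  }
  m
}

#' Dollo gain/loss placement for one presence row
#'
#' The gain node is the MRCA of the present taxa; the loss branches are the
#' roots of the maximal subtrees under the gain node containing no present
#' leaf (the most ancestral attribution, hence the minimum event count for a
#' single-origin model).
#'
#' @param row named 0/1 vector over the tree's leaves, or a character vector
#'   of present taxon ids.
#' @param tree a rooted `phylo` tree.
#' @return an object of class `gain_loss` with `gain_node`, `gain_label`,
#'   `loss_branches` (node numbers), `loss_labels` and `n_losses`.
#' @export
infer_gain_loss <- function(row, tree) {
  if (!ape::is.rooted(tree)) stop2("infer_gain_loss(): tree must be rooted")
  present <- if (is.character(row)) row else names(row)[row > 0]
  if (!length(present)) stop2("infer_gain_loss(): all-absent row")
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown))
    stop2("infer_gain_loss(): taxa not in tree: ",
          paste(unknown, collapse = ", "))
  gain <- mrca_node(tree, present)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  # presence count per subtree (postorder accumulation)
  cnt <- integer(nn)
  cnt[match(present, tree$tip.label)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge)))
    cnt[po$edge[k, 1]] <- cnt[po$edge[k, 1]] + cnt[po$edge[k, 2]]
  kids <- children_of(tree)
  losses <- integer(0)
  stack <- gain
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    for (ch in kids[[n]]) {
      if (cnt[ch] == 0L) losses <- c(losses, ch)
      else if (ch > nt) stack <- c(stack, ch)
    }
  }
  losses <- sort(losses)
  structure(list(gain_node = gain, gain_label = node_label(tree, gain),
                 loss_branches = losses,
                 loss_labels = node_label(tree, losses),
                 n_losses = length(losses)),
            class = "gain_loss")
}

#' @export
print.gain_loss <- function(x, ...) {
  cat(sprintf("<gain_loss> gain at %s; %d losses%s\n", x$gain_label,
              x$n_losses,
              if (x$n_losses) paste0(" (", paste(x$loss_labels, collapse = ", "),
                                     ")") else ""))
  invisible(x)
}

#' Dollo annotations for every row of a presence matrix
#'
#' @param pm a presence matrix from [build_presence_matrix()].
#' @param tree a rooted `phylo` tree whose leaf set equals the matrix columns.
#' @param lgt_ratio diagnostic threshold: a family whose loss count exceeds
#'   `lgt_ratio` times its presence count is flagged as a lateral-transfer
#'   candidate in the `lgt_flag` column.
#' @return data frame with one row per family: `family`, `gain_node`,
#'   `gain_label`, `n_losses`, `loss_labels`, `lgt_flag`, plus the
#'   `annotation` list column of `gain_loss` objects.
#' @export
map_gains <- function(pm, tree, lgt_ratio = 1) {
  if (!setequal(colnames(pm), tree$tip.label))
    stop2("map_gains(): matrix columns must equal the tree's leaf set")
  anns <- lapply(seq_len(nrow(pm)), function(i) infer_gain_loss(pm[i, ], tree))
  out <- data.frame(
    family = rownames(pm) %||% paste0("fam", seq_len(nrow(pm))),
    gain_node = vapply(anns, `[[`, 0L, "gain_node"),
    gain_label = vapply(anns, `[[`, "", "gain_label"),
    n_losses = vapply(anns, `[[`, 0L, "n_losses"),
    loss_labels = vapply(anns, function(a) paste(a$loss_labels, collapse = ","), ""),
    lgt_flag = vapply(seq_len(nrow(pm)), function(i)
      anns[[i]]$n_losses > lgt_ratio * sum(pm[i, ]), TRUE),
    stringsAsFactors = FALSE)
  out$annotation <- anns
  out
}

#' Per-node gain counts (evolutionary-stage summary)
#'
#' @param annotations a data frame from [map_gains()] or a list of
#'   `gain_loss` objects.
#' @param tree the reference tree.
#' @return named integer vector over all nodes of the tree (tips included),
#'   names from [node_label()]; values sum to the number of annotations.
#' @export
summarize_gains <- function(annotations, tree) {
  nodes <- if (is.data.frame(annotations)) annotations$gain_node
           else vapply(annotations, `[[`, 0L, "gain_node")
  nn <- n_tips(tree) + tree$Nnode
  counts <- integer(nn)
  for (n in nodes) {
    if (n < 1 || n > nn) stop2("summarize_gains(): node ", n, " not in tree")
    counts[n] <- counts[n] + 1L
  }
  setNames(counts, node_label(tree, seq_len(nn)))
}

#' Write presence matrix / gain annotations / node summary as TSV
#'
#' @param pm presence matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pm, path) {
  d <- data.frame(family = rownames(pm), pm, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write_tsv(d, path)
}

#' @rdname write_presence_matrix
#' @param gains data frame from [map_gains()].
#' @export
write_gain_annotations <- function(gains, path) {
  d <- as.data.frame(gains)
  d$annotation <- NULL
  write_tsv(d, path)
}

#' @rdname write_presence_matrix
#' @param summary named vector from [summarize_gains()].
#' @export
write_gain_summary <- function(summary, path) {
  write_tsv(data.frame(node = names(summary), gains = unname(summary),
                       stringsAsFactors = FALSE), path)
}
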