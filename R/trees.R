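# Tree plumbing: validated Newick I/O, MRCA queries and outgroup rooting on
# top of ape "phylo" objects. Leaf labels are taxon ids throughout.

#' Parse a Newick tree
#'
#' Wraps [ape::read.tree()] with input validation suited to pipeline use:
#' square-bracket comments are stripped, quoted and internal-node labels are
#' accepted, missing branch lengths default to 0 (topology-only reference
#' trees are legitimate inputs), and malformed input fails with a message
#' naming the problem rather than returning `NULL`.
#'
#' @param text a Newick string terminated by `;`.
#' @param file alternatively, path to a Newick file (first tree read).
#' @return an [ape::read.tree()] `phylo` object with an `edge.length` vector
#'   (0 where the input had none).
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop2("parse_newick(): give text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)   # strip comments
  s <- trimws(text)
  if (!nzchar(s)) stop2("parse_newick(): empty input")
  if (!endsWith(s, ";"))
    stop2("parse_newick(): Newick string must end with ';'")
  chars <- strsplit(s, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop2("parse_newick(): unbalanced parenthesis at position ",
          which(depth < 0)[1])
  if (depth[length(depth)] != 0)
    stop2("parse_newick(): unbalanced parentheses (",
          depth[length(depth)], " unclosed)")
  tr <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop2("parse_newick(): cannot parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop2("parse_newick(): duplicate leaf labels: ",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else {
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0))
    stop2("parse_newick(): negative branch length in input")
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12L) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

n_tips <- function(tree) length(tree$tip.label)

#' Most recent common ancestor of a taxon set
#'
#' @param tree a rooted `phylo` tree.
#' @param taxa non-empty character vector of leaf labels. A single taxon
#'   returns the leaf node itself.
#' @return the ape node number of the MRCA.
#' @export
mrca_node <- function(tree, taxa) {
  if (!ape::is.rooted(tree))
    stop2("mrca_node(): tree is unrooted; root it first ",
          "(see root_with_outgroup())")
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop2("mrca_node(): empty taxon set")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop2("mrca_node(): unknown taxon id: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Human-readable label of a node
#'
#' Tips use their tip label; internal nodes use the Newick node label when
#' present, otherwise `node_<number>`.
#'
#' @param tree a `phylo` object.
#' @param node ape node number(s).
#' @return character vector of labels.
#' @export
node_label <- function(tree, node) {
  nt <- n_tips(tree)
  vapply(node, function(n) {
    if (n <= nt) return(tree$tip.label[n])
    lab <- if (!is.null(tree$node.label)) tree$node.label[n - nt] else ""
    if (is.na(lab) || !nzchar(lab)) paste0("node_", n) else lab
  }, "")
}

#' Node number of a labelled node
#'
#' @param tree a `phylo` object.
#' @param label a tip or internal-node label.
#' @return the ape node number.
#' @export
node_id <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(n_tips(tree) + j)
  }
  stop2("node_id(): no node labelled '", label, "'")
}

# Tip labels under a node (the node itself if a tip).
#' Tips descending from a node
#' @param tree a `phylo` object.
#' @param node an ape node number.
#' @return character vector of tip labels in the node's subtree.
#' @export
tips_under <- function(tree, node) {
  nt <- n_tips(tree)
  if (node <= nt) return(tree$tip.label[node])
  kids <- children_of(tree)
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    if (n <= nt) acc <- c(acc, tree$tip.label[n])
    else stack <- c(stack, kids[[n]])
  }
  sort(acc)
}

# children adjacency list indexed by node number
children_of <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nn)))
}

parent_of <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  p <- rep(NA_integer_, nn)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# Does `tipset` form a clan (one side of some edge) in the unrooted tree?
is_clan <- function(tree, tipset) {
  tipset <- sort(unique(tipset))
  utr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  all_tips <- sort(utr$tip.label)
  if (length(tipset) %in% c(1L, length(all_tips) - 1L)) return(TRUE)
  for (e in seq_len(nrow(utr$edge))) {
    side <- tips_under(utr, utr$edge[e, 2])
    if (identical(side, tipset) ||
        identical(sort(setdiff(all_tips, side)), tipset)) return(TRUE)
  }
  FALSE
}

#' Root an unrooted tree with an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup,
#' splitting that edge at its midpoint. A single-leaf outgroup roots on its
#' pendant edge. An outgroup that does not form a clan (one side of an edge)
#' in the unrooted tree is an error: silent forcing would fabricate a root.
#'
#' @param tree a `phylo` tree (rooted input is unrooted first).
#' @param outgroup character vector of leaf labels, a proper subset of the
#'   tree's leaves.
#' @return a rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  outgroup <- unique(as.character(outgroup))
  unknown <- setdiff(outgroup, tree$tip.label)
  if (length(unknown))
    stop2("root_with_outgroup(): unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(outgroup) >= n_tips(tree))
    stop2("root_with_outgroup(): outgroup must be a proper subset of leaves")
  utr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (!is_clan(utr, outgroup))
    stop2("root_with_outgroup(): outgroup {",
          paste(outgroup, collapse = ","),
          "} does not form a clan in the unrooted tree; refusing to force a root")
  rt <- ape::root(utr, outgroup = outgroup, resolve.root = TRUE)
  # midpoint the two basal edges so the root bisects the original edge
  root_node <- n_tips(rt) + 1L
  basal <- which(rt$edge[, 1] == root_node)
  if (length(basal) == 2L) {
    tot <- sum(rt$edge.length[basal])
    rt$edge.length[basal] <- tot / 2
  }
  rt
}
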