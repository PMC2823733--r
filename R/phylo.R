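# Supermatrix neighbour-joining stage: concatenation of per-gene protein
# alignments, Gblocks-style removal of poorly aligned positions, Kimura
# protein distances, neighbour joining with column-resampling bootstrap, and
# outgroup rooting.

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param msas named list of [as_msa()] matrices (names are gene ids); rows
#'   are taxon ids.
#' @param taxon_policy `"strict"` requires identical taxon sets across genes;
#'   `"pad"` fills taxa absent from a gene with gap columns.
#' @return a list of class `concat_aln`: `msa` (the concatenated matrix) and
#'   `partitions` (data frame `gene`, `start`, `end`; 0-based half-open
#'   intervals tiling the columns).
#' @export
concatenate <- function(msas, taxon_policy = c("strict", "pad")) {
  taxon_policy <- match.arg(taxon_policy)
  stopifnot(is.list(msas), length(msas) >= 1)
  if (is.null(names(msas)) || any(!nzchar(names(msas))))
    stop2("concatenate(): alignments must be named by gene id")
  if (anyDuplicated(names(msas)))
    stop2("concatenate(): duplicate gene ids: ",
          paste(unique(names(msas)[duplicated(names(msas))]), collapse = ", "))
  taxa_sets <- lapply(msas, rownames)
  all_taxa <- unique(unlist(taxa_sets))   # order of first appearance
  if (taxon_policy == "strict") {
    for (g in names(msas)) {
      miss <- setdiff(all_taxa, taxa_sets[[g]])
      if (length(miss))
        stop2("concatenate(): taxon '", miss[1L], "' missing from gene '",
              g, "' (strict mode)")
    }
  }
  widths <- vapply(msas, ncol, 0L)
  total <- sum(widths)
  out <- matrix("-", nrow = length(all_taxa), ncol = total,
                dimnames = list(all_taxa, NULL))
  at <- 0L
  parts <- data.frame(gene = names(msas), start = integer(length(msas)),
                      end = integer(length(msas)), stringsAsFactors = FALSE)
  for (i in seq_along(msas)) {
    m <- unclass(msas[[i]])
    out[rownames(m), at + seq_len(ncol(m))] <- m
    parts$start[i] <- at
    parts$end[i] <- at + ncol(m)
    at <- at + ncol(m)
  }
  structure(list(msa = as_msa(out), partitions = parts),
            class = "concat_aln")
}

#' Parameters of the block filter
#'
#' Defaults reconstruct the published description of the Gblocks 0.91b
#' defaults for an alignment of `n` sequences, with the allowed-gap mode set
#' to `"half"` (a position is kept only when its gap fraction is at most
#' 0.5). Exact dialect fidelity to the original binary is not claimed; every
#' knob is exposed.
#'
#' @param n number of sequences the filter will be applied to.
#' @param b1 minimum count of the modal residue for a conserved position
#'   (default `floor(n/2) + 1`).
#' @param b2 minimum count for a highly conserved (flank) position
#'   (default `ceiling(0.85 * n)`).
#' @param b3 maximum length of a contiguous run of nonconserved positions
#'   (default 8).
#' @param b4 minimum block length (default 10).
#' @param gap_mode `"none"` keeps only gap-free positions, `"half"` keeps
#'   positions with gap fraction <= 0.5, `"all"` ignores gaps.
#' @return an object of class `block_filter_params`.
#' @export
block_filter_params <- function(n, b1 = floor(n / 2) + 1,
                                b2 = ceiling(0.85 * n), b3 = 8L, b4 = 10L,
                                gap_mode = c("half", "none", "all")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(n >= 2, b1 <= b2, b2 <= n, b3 >= 1, b4 >= 2)
  structure(list(n = as.integer(n), b1 = as.integer(b1), b2 = as.integer(b2),
                 b3 = as.integer(b3), b4 = as.integer(b4),
                 gap_mode = gap_mode),
            class = "block_filter_params")
}

#' Remove poorly aligned alignment positions (Gblocks-style)
#'
#' Procedure: (1) drop columns failing the gap mode; (2) classify surviving
#' columns by the count of their modal residue — nonconserved below `b1`,
#' highly conserved at or above `b2`, conserved between; (3) remove contiguous
#' nonconserved stretches longer than `b3` (contiguity measured among the
#' surviving columns); (4) trim each remaining block's ends inward to the
#' first/last highly conserved column; (5) drop blocks shorter than `b4`.
#'
#' @param aln an [as_msa()] matrix with at least 4 sequences.
#' @param params a [block_filter_params()] object (defaults computed from
#'   `nrow(aln)`).
#' @return a list: `msa` (filtered alignment) and `kept` (1-based indices of
#'   retained input columns, in order).
#' @export
filter_blocks <- function(aln, params = block_filter_params(nrow(aln))) {
  stopifnot(inherits(aln, "msa"))
  m <- unclass(aln)
  if (nrow(m) < 4) stop2("filter_blocks(): need >= 4 sequences")
  stopifnot(inherits(params, "block_filter_params"))
  gap_frac <- colMeans(m == "-")
  cols <- switch(params$gap_mode,
    none = which(gap_frac == 0),
    half = which(gap_frac <= 0.5),
    all = seq_len(ncol(m)))
  if (!length(cols)) {
    warning("filter_blocks(): no columns survive the gap filter")
    return(list(msa = as_msa(m[, integer(0), drop = FALSE]), kept = integer(0)))
  }
  mode_count <- vapply(cols, function(j) {
    res <- m[, j]; res <- res[res != "-"]
    if (!length(res)) 0L else as.integer(max(table(res)))
  }, 0L)
  cls <- ifelse(mode_count < params$b1, "N",
                ifelse(mode_count >= params$b2, "H", "C"))
  # (3) strip long nonconserved stretches, contiguity among surviving columns
  keep <- rep(TRUE, length(cols))
  r <- rle(cls == "N")
  pos <- cumsum(r$lengths) - r$lengths + 1L
  for (k in seq_along(r$lengths))
    if (r$values[k] && r$lengths[k] > params$b3)
      keep[pos[k]:(pos[k] + r$lengths[k] - 1L)] <- FALSE
  # (4)+(5) blocks delimited by the removed stretches
  kept_idx <- integer(0)
  b <- rle(keep)
  bpos <- cumsum(b$lengths) - b$lengths + 1L
  for (k in seq_along(b$lengths)) {
    if (!b$values[k]) next
    i0 <- bpos[k]; i1 <- bpos[k] + b$lengths[k] - 1L
    block <- i0:i1
    hc <- which(cls[block] == "H")
    if (!length(hc)) next
    block <- block[hc[1L]:hc[length(hc)]]
    if (length(block) < params$b4) next
    kept_idx <- c(kept_idx, block)
  }
  kept <- cols[kept_idx]
  if (!length(kept)) warning("filter_blocks(): empty filtered alignment")
  list(msa = as_msa(m[, kept, drop = FALSE]), kept = kept)
}

#' Kimura protein distances
#'
#' For each pair, `p` is the fraction of differing sites among sites where
#' neither sequence has a gap (pairwise deletion) or among gap-free columns
#' (complete deletion); the distance is `d = -ln(1 - p - 0.2 p^2)`. The
#' correction diverges at `p >= (sqrt(1.8) - 1)/0.4 ~= 0.854`; such pairs are
#' an error, not silently capped — capping distorts neighbour joining.
#'
#' @param aln an [as_msa()] matrix with at least 2 sequences.
#' @param site_policy `"pairwise_deletion"` (default) or
#'   `"complete_deletion"`.
#' @return symmetric numeric matrix of distances with zero diagonal.
#' @export
pairwise_kimura <- function(aln,
                            site_policy = c("pairwise_deletion",
                                            "complete_deletion")) {
  site_policy <- match.arg(site_policy)
  stopifnot(inherits(aln, "msa"))
  m <- unclass(aln)
  if (nrow(m) < 2) stop2("pairwise_kimura(): need >= 2 sequences")
  if (site_policy == "complete_deletion") {
    m <- m[, colSums(m == "-") == 0, drop = FALSE]
  }
  n <- nrow(m)
  ids <- rownames(m)
  # indicator cross-products: comparable-site and identical-site counts for
  # all pairs at once (the per-pair loop dominates bootstrap runtime)
  ok <- (m != "-") * 1
  V <- tcrossprod(ok)                     # sites with neither gapped
  M <- matrix(0, n, n)
  for (a in AA_LETTERS) {
    Xa <- (m == a) * 1
    M <- M + tcrossprod(Xa)               # sites identical (and ungapped)
  }
  off <- upper.tri(V)
  if (any(V[off] == 0)) {
    bad <- which(V == 0 & off, arr.ind = TRUE)[1L, ]
    stop2("pairwise_kimura(): no comparable sites for pair ", ids[bad[1]],
          " / ", ids[bad[2]])
  }
  P <- (V - M) / V
  arg <- 1 - P - 0.2 * P^2
  if (any(arg[off] <= 0)) {
    bad <- which(arg <= 0 & off, arr.ind = TRUE)[1L, ]
    stop2("pairwise_kimura(): p = ", signif(P[bad[1], bad[2]], 4),
          " for pair ", ids[bad[1]], " / ", ids[bad[2]],
          " is outside the Kimura correction domain (p < 0.854)")
  }
  D <- -log(arg)
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

#' Neighbour-joining tree
#'
#' Standard rate-corrected neighbour joining (Q criterion, iterative
#' agglomeration). Ties in Q are broken deterministically by the smallest
#' (row, column) index pair in the current matrix (merged nodes take the
#' smaller slot). Negative branch lengths are clamped to 0 with a warning.
#'
#' @param D symmetric distance matrix with taxon dimnames, `n >= 3`, no
#'   `NA`/`NaN` entries.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop2("nj_tree(): D must be square")
  if (anyNA(D)) stop2("nj_tree(): NA/NaN entries in distance matrix")
  if (nrow(D) < 3) stop2("nj_tree(): need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop2("nj_tree(): matrix not symmetric")
  labs <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  frag <- labs
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.15g", x)
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    rs <- rowSums(D)
    Q <- (n - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    newfrag <- paste0("(", frag[i], ":", bl(li), ",", frag[j], ":", bl(lj), ")")
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    dk <- dk[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dk), c(dk, 0))
    frag <- c(frag[-c(i, j)], newfrag)
    # move the merged node into the smaller vacated slot for determinism
    ord <- c(seq_len(nrow(D) - 1L), nrow(D))
    if (i <= nrow(D) - 1L) {
      ord <- append(seq_len(nrow(D) - 1L), nrow(D), after = i - 1L)
      D <- D[ord, ord, drop = FALSE]
      frag <- frag[ord]
    }
  }
  # terminal 3-star: closed-form limb lengths
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", bl(x), ",", frag[2], ":", bl(y), ",",
                frag[3], ":", bl(z), ");")
  if (clamped) warning("nj_tree(): negative branch length(s) clamped to 0")
  tr <- ape::read.tree(text = nwk)
  tr
}

#' Canonical key of a bipartition
#'
#' The key names the side of the split that does not contain the
#' alphabetically first tip, sorted and joined with `|`; both sides of a
#' bipartition therefore map to the same key. Used to look supports up in
#' [bootstrap_support()] output.
#'
#' @param side tip labels of one side of the split.
#' @param all_tips all tip labels of the tree.
#' @return a string key.
#' @export
split_key <- function(side, all_tips) {
  ref <- min(all_tips)
  s <- sort(side)
  if (ref %in% s) s <- sort(setdiff(all_tips, s))
  paste(s, collapse = "|")
}

# keys of all internal bipartitions of an (unrooted) tree
tree_splits <- function(tree) {
  utr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  nt <- n_tips(utr)
  all_tips <- utr$tip.label
  internal <- which(utr$edge[, 2] > nt)
  keys <- vapply(internal, function(e)
    split_key(tips_under(utr, utr$edge[e, 2]), all_tips), "")
  unique(keys)
}

#' Bootstrap support for the bipartitions of an alignment's NJ tree
#'
#' Columns are resampled with replacement to the original alignment length;
#' distances and the NJ tree are recomputed for each replicate; support for
#' each internal bipartition of the original tree is the percentage of
#' replicates containing it. Supports are mapped onto the original tree's
#' bipartitions (not a consensus tree), matching the "numbers at the nodes"
#' convention.
#'
#' @param aln an [as_msa()] matrix.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed optional integer seed for reproducible resampling.
#' @param site_policy passed to [pairwise_kimura()].
#' @return a list: `tree` (the original NJ tree with internal node labels set
#'   to the support percentages) and `support` (named numeric vector,
#'   bipartition key -> percent).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = NULL,
                              site_policy = "pairwise_deletion") {
  stopifnot(inherits(aln, "msa"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  base_tree <- nj_tree(pairwise_kimura(aln, site_policy))
  keys <- tree_splits(base_tree)
  counts <- setNames(numeric(length(keys)), keys)
  m <- unclass(aln)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- as_msa(m[, idx, drop = FALSE])
    rep_tree <- suppressWarnings(nj_tree(pairwise_kimura(rep_aln, site_policy)))
    rk <- tree_splits(rep_tree)
    hit <- keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  # attach supports as internal node labels of the original tree
  utr <- if (ape::is.rooted(base_tree)) ape::unroot(base_tree) else base_tree
  nt <- n_tips(utr)
  labs <- character(utr$Nnode)
  for (nd in (nt + 1L):(nt + utr$Nnode)) {
    key <- split_key(tips_under(utr, nd), utr$tip.label)
    if (key %in% names(support) && nzchar(key))
      labs[nd - nt] <- sprintf("%g", support[[key]])
  }
  utr$node.label <- labs
  list(tree = utr, support = support)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(format(rownames(D)[i], width = 12),
                       sprintf("%.8f", D[i, ])), collapse = " "), con)
  invisible(path)
}
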