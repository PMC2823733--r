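# Synthetic-data generator: a clade-structured species tree in the image of
# the cyanobacterial reference topology (outgroup pair; deepest-branching
# Clade A; Clade B containing the NOC subclade of Nostocales, Oscillatoriales
# and Chroococcales; the elongatus pair; Clade C of marine picocyanobacteria
# containing the low B/A ecotype), universal housekeeping families, families
# gained at chosen internal nodes with optional losses, ORFans, planted indels
# with frozen conserved flanks, and simulated homology hit tables with
# configurable decoy noise. Everything is seeded and every planted fact is
# recorded in a machine-readable truth bundle.

default_tree_template <- function() {
  leaf <- function(prefix, n, len)
    paste0(prefix, seq_len(n), ":", len, collapse = ",")
  paste0(
    "((OUT1:0.15,OUT2:0.15)Outgroup:0.40,",
    "((GLV:0.10,(SJA:0.05,SJB:0.05)SJpair:0.06)CladeA:0.12,",
    "((((THE:0.10,(ACA:0.08,SPC:0.08)BX1:0.03)Bother:0.04,",
    "((", leaf("CHR", 5, 0.06), ")Chroococcales:0.05,",
    "((", leaf("OSC", 3, 0.05), ")Oscillatoriales:0.04,",
    "(", leaf("NOS", 5, 0.05), ")Nostocales:0.04)OscNos:0.03",
    ")NOC:0.05)CladeB:0.05,",
    "(ELO1:0.06,ELO2:0.06)Elongatus:0.08)BElo:0.05,",
    "((", leaf("SYN", 10, 0.07), ")Syn:0.05,",
    "((MIT1:0.04,MIT2:0.04)MIT:0.05,",
    "((", leaf("HBA", 5, 0.05), ")HBA:0.05,",
    "(", leaf("LBA", 6, 0.04), ")LowBA:0.10)ProExMIT:0.04",
    ")Pro:0.06)CladeC:0.08)R1:0.04)Cyano:0.25)Root;")
}

default_clades <- function() {
  noc <- c(paste0("CHR", 1:5), paste0("OSC", 1:3), paste0("NOS", 1:5))
  cladeb <- c("THE", "ACA", "SPC", noc)
  cladec <- c(paste0("SYN", 1:10), "MIT1", "MIT2", paste0("HBA", 1:5),
              paste0("LBA", 1:6))
  list(
    Outgroup = c("OUT1", "OUT2"),
    CladeA = c("GLV", "SJA", "SJB"),
    Nostocales = paste0("NOS", 1:5),
    Oscillatoriales = paste0("OSC", 1:3),
    Chroococcales = paste0("CHR", 1:5),
    NOC = noc,
    CladeB = cladeb,
    Elongatus = c("ELO1", "ELO2"),
    Syn = paste0("SYN", 1:10),
    MIT = c("MIT1", "MIT2"),
    ProExMIT = c(paste0("HBA", 1:5), paste0("LBA", 1:6)),
    Pro = c("MIT1", "MIT2", paste0("HBA", 1:5), paste0("LBA", 1:6)),
    LowBA = paste0("LBA", 1:6),
    CladeC = cladec,
    Cyano = c("GLV", "SJA", "SJB", cladeb, "ELO1", "ELO2", cladec))
}

default_targets <- function() {
  c("CladeA", "Nostocales", "Chroococcales", "LowBA", "NOC", "CladeB",
    "CladeB+Elongatus", "CladeC-LowBA", "CladeC", "Cyano-CladeA", "Cyano")
}

default_indels <- function() {
  list(
    list(family = "U001", node = "CladeC", length = 6L, type = "insertion"),
    list(family = "U002", node = "CladeB", length = 2L, type = "insertion"),
    list(family = "U003", node = "ProExMIT", length = 1L, type = "deletion"),
    list(family = "U004", node = "R1", length = 5L, type = "insertion",
         degrade = 1L))
}

#' Scenario configuration for the synthetic-data generator
#'
#' The defaults state the benchmark world: a 46-taxon species tree mirroring
#' the reference clade hierarchy (2 outgroup taxa, 44 ingroup), 40 universal
#' housekeeping families, 10 families planted at each of 11 specificity
#' targets (including the compound targets all-minus-CladeA,
#' CladeB-plus-elongatus and CladeC-minus-LowBA), 20 ORFans, four planted
#' indels of lengths 6, 2, 1 (a deletion) and 4--5 residues with frozen
#' 5-column flanks, 300-residue root sequences and no decoy hits.
#'
#' @param tree_template Newick string with named internal nodes and branch
#'   lengths in substitutions/site.
#' @param clades named list of taxon sets (the clade definitions).
#' @param targets character vector of clade-expression strings, the CSP
#'   specificity targets in listed order.
#' @param planted named integer vector: families to plant per target
#'   (default 10 each).
#' @param n_universal number of universal families present in every taxon.
#' @param n_orfans number of single-taxon families.
#' @param losses list of `list(family=, node=)` records: members under `node`
#'   are deleted from the family after planting.
#' @param indels list of `list(family=, node=, length=, type=, degrade=)`
#'   records; `type` is `"insertion"` or `"deletion"`, `degrade` (insertions
#'   only) gives that many carriers a 1-residue internal gap, turning a
#'   length-L indel into an L-1..L range.
#' @param flank_width frozen conserved flank width for planted indels.
#' @param root_len root sequence length (aa).
#' @param decoy_rate probability of a decoy hit per non-homologous ordered
#'   pair.
#' @param e_model named vector `c(a=, b=, sigma=)` of the phenomenological
#'   E-value model `E = 10^-(a + b*s + eps)`, `s` the identity fraction and
#'   `eps ~ Normal(0, sigma^2)` truncated at 3 sigma.
#' @param query_taxa taxa whose full proteomes are used as CSP queries (one
#'   tip per major clade, mirroring the six query genomes of the original
#'   protocol).
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   the configuration including the seed.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(tree_template = default_tree_template(),
                            clades = default_clades(),
                            targets = default_targets(),
                            planted = setNames(rep(10L, length(targets)),
                                               targets),
                            n_universal = 40L, n_orfans = 20L,
                            losses = list(), indels = default_indels(),
                            flank_width = 5L, root_len = 300L,
                            decoy_rate = 0,
                            e_model = c(a = 5, b = 100, sigma = 2),
                            query_taxa = c("SJA", "CHR1", "NOS1", "SYN1",
                                           "LBA1", "HBA1"),
                            seed = 1L) {
  stopifnot(root_len >= 1, n_universal >= 0, n_orfans >= 0,
            decoy_rate >= 0, decoy_rate <= 1,
            all(c("a", "b", "sigma") %in% names(e_model)))
  structure(list(tree_template = tree_template, clades = clades,
                 targets = targets, planted = planted,
                 n_universal = as.integer(n_universal),
                 n_orfans = as.integer(n_orfans), losses = losses,
                 indels = indels, flank_width = as.integer(flank_width),
                 root_len = as.integer(root_len), decoy_rate = decoy_rate,
                 e_model = e_model, query_taxa = query_taxa,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Evolve a protein family down a tree
#'
#' The root sequence is uniform over the 20 amino-acid letters. Along a branch
#' of length `t`, each site independently substitutes with probability
#' `1 - exp(-t)`; on substitution the new letter is uniform over the 20
#' letters (so a substitution event is silent with probability 1/20, identity
#' decays to 1/20 at saturation, and the identity between two leaves joined by
#' a path of total length T has the closed form `exp(-T) + (1-exp(-T))/20`).
#' The true alignment is the site-wise correspondence: the model itself
#' introduces no indels.
#'
#' Uses the R global random number generator; seed with [set.seed()] (or let
#' [generate_scenario()] do it).
#'
#' @param tree a rooted `phylo` tree with branch lengths >= 0.
#' @param root_len sequence length (aa).
#' @return a list: `msa` (character matrix, rows = tips), `n_events` (total
#'   substitution events drawn) and `n_site_branch` (sites times branches,
#'   the denominator of the event rate).
#' @export
evolve_family <- function(tree, root_len = 300L) {
  stopifnot(ape::is.rooted(tree), all(tree$edge.length >= 0))
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  L <- as.integer(root_len)
  seqs <- matrix(NA_character_, nrow = nn, ncol = L)
  root <- nt + 1L
  seqs[root, ] <- sample(AA_LETTERS, L, replace = TRUE)
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  n_events <- 0L
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    t <- ord$edge.length[k]
    s <- seqs[par, ]
    hit <- runif(L) < (1 - exp(-t))
    if (any(hit)) s[hit] <- sample(AA_LETTERS, sum(hit), replace = TRUE)
    n_events <- n_events + sum(hit)
    seqs[ch, ] <- s
  }
  msa <- seqs[seq_len(nt), , drop = FALSE]
  rownames(msa) <- tree$tip.label
  list(msa = msa, n_events = n_events,
       n_site_branch = L * nrow(tree$edge))
}

#' Plant a conserved indel into a family alignment
#'
#' For an insertion, every leaf under `node` receives the same random segment
#' of `length` residues at a locus at least `flank` columns from either end;
#' all other members receive gap columns there. For a deletion, leaves under
#' `node` get gaps over an existing `length`-column window while everyone else
#' keeps residues. The `flank` columns on each side are frozen to a single
#' conserved motif across all members, guaranteeing gap-free, fully conserved
#' flanks. Optionally, `degrade` carriers receive a 1-residue internal gap
#' (insertions only), making the indel a length range.
#'
#' Uses the R global random number generator.
#'
#' @param msa character matrix of the family's true alignment (rows =
#'   members).
#' @param tree the species tree (for resolving `node` to carrier taxa).
#' @param node internal node label (or tip label) of the carrier subtree.
#' @param length indel length in residues.
#' @param flank frozen flank width in columns.
#' @param type `"insertion"` or `"deletion"`.
#' @param degrade number of carriers given a 1-residue internal gap.
#' @return a list: `msa` (modified alignment) and `truth` (locus record:
#'   `start`/`end` 0-based half-open, `len_min`, `len_max`, `polarity`,
#'   `carriers`, `clade` = member taxa under `node`, `tau_required`).
#' @export
plant_indel <- function(msa, tree, node, length, flank = 5L,
                        type = c("insertion", "deletion"), degrade = 0L) {
  type <- match.arg(type)
  len <- as.integer(length)
  rm(length)   # unshadow base::length
  L <- ncol(msa)
  members <- rownames(msa)
  under <- intersect(tips_under(tree, node_id(tree, node)), members)
  others <- setdiff(members, under)
  if (!length(under))
    stop2("plant_indel(): no family member under node '", node, "'")
  if (type == "deletion" && !length(others))
    stop2("plant_indel(): a deletion needs non-carrier members")
  if (L < 2 * flank + len + 2)
    stop2("plant_indel(): sequence too short for locus plus flanks")
  motif <- function(w) sample(AA_LETTERS, w, replace = TRUE)
  if (type == "insertion") {
    k <- sample(seq(flank, L - flank), 1L)     # insert after column k
    seg <- motif(len)
    ins <- matrix("-", nrow = nrow(msa), ncol = len)
    ins[match(under, members), ] <- matrix(seg, nrow = length(under),
                                           ncol = len, byrow = TRUE)
    out <- cbind(msa[, seq_len(k), drop = FALSE], ins,
                 msa[, seq(k + 1L, L), drop = FALSE])
    s0 <- k            # 0-based start of the region
    e0 <- k + len
    carriers <- under
  } else {
    s1 <- sample(seq(flank + 1L, L - len - flank + 1L), 1L)
    out <- msa
    out[match(under, members), s1:(s1 + len - 1L)] <- "-"
    s0 <- s1 - 1L
    e0 <- s0 + len
    carriers <- others
  }
  # freeze flanks to a conserved motif across every member
  lcols <- (s0 - flank + 1L):s0
  rcols <- (e0 + 1L):(e0 + flank)
  out[, lcols] <- matrix(motif(flank), nrow = nrow(out), ncol = flank,
                         byrow = TRUE)
  out[, rcols] <- matrix(motif(flank), nrow = nrow(out), ncol = flank,
                         byrow = TRUE)
  len_min <- len; len_max <- len
  tau_required <- 0
  if (type == "insertion" && degrade > 0) {
    if (degrade >= length(under) || len < 3)
      stop2("plant_indel(): cannot degrade ", degrade, " of ",
            length(under), " carriers")
    victims <- sample(under, degrade)
    gcol <- s0 + sample(seq(2L, len - 1L), 1L)   # internal region column
    out[match(victims, members), gcol] <- "-"
    len_min <- len - 1L
    tau_required <- degrade / length(under)
  }
  list(msa = out,
       truth = list(node = node, type = type, start = s0, end = e0,
                    len_min = len_min, len_max = len_max,
                    polarity = if (type == "insertion") "insert_in_clade"
                               else "deletion_in_clade",
                    clade = sort(under), carriers = sort(carriers),
                    tau_required = tau_required))
}

# pairwise identity fractions over both-non-gap columns
family_identities <- function(msa) {
  n <- nrow(msa)
  gap <- msa == "-"
  s <- matrix(1, n, n, dimnames = list(rownames(msa), rownames(msa)))
  len <- matrix(ncol(msa), n, n, dimnames = dimnames(s))
  if (n < 2) return(list(s = s, len = len))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      len[i, j] <- len[j, i] <- sum(ok)
      s[i, j] <- s[j, i] <- if (any(ok)) mean(msa[i, ok] == msa[j, ok]) else 0
    }
  }
  list(s = s, len = len)
}

#' Emit a simulated homology hit table
#'
#' For every ordered pair of members of the same family, one 13-column hit row
#' is emitted with percent identity computed from the true sequences and
#' `E = 10^-(a + b*s + eps)` (`s` the identity fraction, `eps` normal with sd
#' `sigma` truncated at 3 sigma), clipped to `[1e-180, 1]`. With decoy rate
#' `rho > 0`, each non-homologous ordered pair independently emits, with
#' probability `rho`, a decoy row with E-value log-uniform on `[1e-4, 10]`.
#'
#' Uses the R global random number generator.
#'
#' @param families list of family records, each `list(id=, msa=)` with member
#'   taxa as the alignment row names; member sequence ids are
#'   `"<taxon>|<family>"`.
#' @param e_model named vector `c(a=, b=, sigma=)`.
#' @param rho decoy rate in `[0, 1]`.
#' @return a data frame of class `hit_table` with an extra logical column
#'   `homolog` (the per-row truth flag; drop it when writing the 13-column
#'   TSV via [write_hit_table()]).
#' @export
emit_hit_table <- function(families, e_model = c(a = 5, b = 100, sigma = 2),
                           rho = 0) {
  a <- e_model[["a"]]; b <- e_model[["b"]]; sig <- e_model[["sigma"]]
  rows <- list()
  seq_len_of <- list()
  fam_of <- list()
  for (f in families) {
    ung <- rowSums(f$msa != "-")
    for (tx in rownames(f$msa)) {
      sid <- paste0(tx, "|", f$id)
      seq_len_of[[sid]] <- ung[[tx]]
      fam_of[[sid]] <- f$id
    }
    m <- nrow(f$msa)
    if (m < 2) next
    idn <- family_identities(f$msa)
    prs <- which(upper.tri(idn$s), arr.ind = TRUE)
    prs <- rbind(prs, prs[, 2:1, drop = FALSE])   # both directions
    np <- nrow(prs)
    eps <- rnorm(np, 0, sig)
    eps <- pmax(pmin(eps, 3 * sig), -3 * sig)
    s <- idn$s[prs]
    alen <- idn$len[prs]
    E <- pmin(pmax(10^(-(a + b * s + eps)), 1e-180), 1)
    qtx <- rownames(f$msa)[prs[, 1]]
    stx <- rownames(f$msa)[prs[, 2]]
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = paste0(qtx, "|", f$id),
      subject_id = paste0(stx, "|", f$id),
      pident = round(100 * s, 1), length = as.integer(alen),
      mismatch = as.integer(round((1 - s) * alen)), gapopen = 0L,
      qstart = 1L, qend = as.integer(ung[qtx]),
      sstart = 1L, send = as.integer(ung[stx]),
      evalue = E, bitscore = round(2 * s * alen, 1),
      subject_length = as.integer(ung[stx]),
      homolog = TRUE, stringsAsFactors = FALSE)
  }
  if (rho > 0) {
    ids <- names(seq_len_of)
    fam <- unlist(fam_of[ids])
    n <- length(ids)
    if (n > 3000)
      stop2("emit_hit_table(): decoy enumeration over ", n,
            " sequences is quadratic; lower the scale or rho")
    qi <- rep(seq_len(n), each = n)
    si <- rep(seq_len(n), times = n)
    keep <- fam[qi] != fam[si]
    qi <- qi[keep]; si <- si[keep]
    pick <- runif(length(qi)) < rho
    qi <- qi[pick]; si <- si[pick]
    if (length(qi)) {
      E <- 10^runif(length(qi), -4, 1)
      alen <- pmax(20L, as.integer(round(
        pmin(unlist(seq_len_of[ids[qi]]), unlist(seq_len_of[ids[si]])) *
          runif(length(qi), 0.2, 0.5))))
      s <- runif(length(qi), 0.15, 0.30)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = ids[qi], subject_id = ids[si],
        pident = round(100 * s, 1), length = alen,
        mismatch = as.integer(round((1 - s) * alen)), gapopen = 0L,
        qstart = 1L, qend = alen, sstart = 1L, send = alen,
        evalue = E, bitscore = round(2 * s * alen, 1),
        subject_length = unname(unlist(seq_len_of[ids[si]])),
        homolog = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    query_id = character(0), subject_id = character(0), pident = numeric(0),
    length = integer(0), mismatch = integer(0), gapopen = integer(0),
    qstart = integer(0), qend = integer(0), sstart = integer(0),
    send = integer(0), evalue = numeric(0), bitscore = numeric(0),
    subject_length = integer(0), homolog = logical(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Write a hit table as 13-column TSV
#'
#' @param hits a `hit_table` data frame (a `homolog` truth column, if present,
#'   is dropped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  h <- as.data.frame(hits)
  h$homolog <- NULL
  h$evalue <- format_evalue(h$evalue)
  write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Generate a full synthetic scenario with ground truth
#'
#' Evolves every family down the species tree, applies planted losses and
#' indels, emits per-taxon proteome FASTAs, per-family true alignments, a
#' 13-column hit table, taxonomy and clade TSVs, the reference Newick, a query
#' list and a truth JSON. The bundle is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created); when `NULL`, nothing is written and
#'   only the in-memory bundle is returned.
#' @return (invisibly when writing) a list: `tree`, `map` ([taxonomy_map()]),
#'   `defs` ([clade_defs()]), `families` (list of `id`/`type`/`target`/`msa`),
#'   `hits` (`hit_table` with truth flag), `queries` (data frame), `truth`
#'   (list mirrored in `truth.json`) and `paths` (named file paths, when
#'   written).
#' @export
generate_scenario <- function(config = scenario_config(), dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  tree <- parse_newick(config$tree_template)
  taxa <- sort(tree$tip.label)
  missing_clade_taxa <- setdiff(unique(unlist(config$clades)), taxa)
  if (length(missing_clade_taxa))
    stop2("generate_scenario(): clade taxa not in tree: ",
          paste(missing_clade_taxa, collapse = ", "))
  defs <- clade_defs(config$clades, all_taxa = taxa)
  ingroup <- if ("Cyano" %in% names(config$clades)) config$clades$Cyano
             else setdiff(taxa, config$clades$Outgroup %||% character(0))

  fams <- list()
  add_family <- function(id, type, target, presence) {
    fams[[id]] <<- list(id = id, type = type, target = target,
                        presence = sort(presence))
  }
  for (i in seq_len(config$n_universal))
    add_family(sprintf("U%03d", i), "universal", NA_character_, taxa)
  for (tg in names(config$planted)) {
    pres <- resolve_clade(tg, defs)
    for (i in seq_len(config$planted[[tg]]))
      add_family(sprintf("P_%s_%02d", sanitize_id(tg), i), "planted", tg, pres)
  }
  for (i in seq_len(config$n_orfans))
    add_family(sprintf("ORF%03d", i), "orfan", NA_character_,
               sample(ingroup, 1L))

  # losses: drop the subtree's members from the family
  for (lo in config$losses) {
    f <- fams[[lo$family]]
    if (is.null(f)) stop2("generate_scenario(): loss names unknown family ",
                          lo$family)
    gone <- tips_under(tree, node_id(tree, lo$node))
    if (!all(gone %in% f$presence))
      stop2("generate_scenario(): loss subtree '", lo$node,
            "' is not under the gain node of family ", lo$family)
    left <- setdiff(f$presence, gone)
    if (!length(left))
      stop2("generate_scenario(): loss would empty family ", lo$family)
    fams[[lo$family]]$presence <- left
    fams[[lo$family]]$losses <- c(f$losses, lo$node)
  }

  # evolve + indels
  indel_truth <- list()
  for (id in names(fams)) {
    ev <- evolve_family(tree, config$root_len)
    msa <- ev$msa[fams[[id]]$presence, , drop = FALSE]
    fams[[id]]$msa <- msa
  }
  for (ind in config$indels) {
    f <- fams[[ind$family]]
    if (is.null(f)) stop2("generate_scenario(): indel names unknown family ",
                          ind$family)
    pl <- plant_indel(f$msa, tree, ind$node, ind$length,
                      flank = config$flank_width,
                      type = ind$type %||% "insertion",
                      degrade = ind$degrade %||% 0L)
    fams[[ind$family]]$msa <- pl$msa
    rec <- pl$truth
    rec$family <- ind$family
    indel_truth[[length(indel_truth) + 1L]] <- rec
  }

  # sequences, taxonomy, hits
  seq_rows <- list()
  for (f in fams) {
    for (tx in rownames(f$msa))
      seq_rows[[length(seq_rows) + 1L]] <-
        c(paste0(tx, "|", f$id), tx)
  }
  seq_df <- do.call(rbind, seq_rows)
  map <- taxonomy_map(seq_df[, 1], seq_df[, 2])
  hits <- emit_hit_table(fams, config$e_model, config$decoy_rate)

  queries <- do.call(rbind, lapply(fams, function(f) {
    tx <- intersect(rownames(f$msa), config$query_taxa)
    if (!length(tx)) return(NULL)
    data.frame(query_id = paste0(tx, "|", f$id), taxon = tx,
               length = rowSums(f$msa[tx, , drop = FALSE] != "-"),
               family = f$id, stringsAsFactors = FALSE)
  }))
  if (is.null(queries))
    queries <- data.frame(query_id = character(0), taxon = character(0),
                          length = numeric(0), family = character(0),
                          stringsAsFactors = FALSE)
  queries <- queries[order(queries$query_id), , drop = FALSE]
  rownames(queries) <- NULL

  truth <- list(
    seed = config$seed,
    counts = list(universal = config$n_universal,
                  planted = sum(config$planted),
                  orfans = config$n_orfans,
                  families = length(fams)),
    targets = as.character(config$targets),
    query_taxa = config$query_taxa,
    families = lapply(fams, function(f) {
      gl <- infer_gain_loss(f$presence, tree)
      list(type = f$type, target = f$target, taxa = f$presence,
           gain_node = gl$gain_label, n_losses = gl$n_losses,
           loss_nodes = gl$loss_labels)
    }),
    indels = indel_truth)

  bundle <- list(tree = tree, map = map, defs = defs, families = fams,
                 hits = hits, queries = queries, truth = truth,
                 config = config)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "proteomes"), showWarnings = FALSE)
    dir.create(file.path(dir, "msas"), showWarnings = FALSE)
    paths <- list(
      tree = file.path(dir, "tree.nwk"),
      taxonomy = file.path(dir, "taxonomy.tsv"),
      clades = file.path(dir, "clades.tsv"),
      hits = file.path(dir, "hits.tsv"),
      queries = file.path(dir, "queries.tsv"),
      truth = file.path(dir, "truth.json"))
    write_newick(tree, paths$tree)
    write_taxonomy_map(map, paths$taxonomy)
    write_clade_definitions(defs, paths$clades)
    write_hit_table(hits, paths$hits)
    write_tsv(queries, paths$queries)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    prote <- list()
    for (f in fams) {
      write_fasta(f$msa, file.path(dir, "msas", paste0(f$id, ".afa")))
      sqs <- gsub("-", "", msa_strings(as_msa(f$msa)), fixed = TRUE)
      for (tx in names(sqs))
        prote[[tx]] <- c(prote[[tx]],
                         setNames(sqs[[tx]], paste0(tx, "|", f$id)))
    }
    for (tx in names(prote))
      write_fasta(prote[[tx]], file.path(dir, "proteomes", paste0(tx, ".faa")))
    bundle$paths <- paths
  }
  invisible(bundle)
}

#' Self-audit a generated scenario bundle
#'
#' Re-derives every truth record from the emitted objects: family presence
#' sets match the alignments, indel regions show the planted gap pattern with
#' gap-free identical flanks, ORFans have one member, and (at decoy rate 0)
#' no hit row joins two families.
#'
#' @param bundle the return value of [generate_scenario()].
#' @return `TRUE` (invisibly) or an error describing the first inconsistency.
#' @export
verify_scenario <- function(bundle) {
  for (id in names(bundle$families)) {
    f <- bundle$families[[id]]
    tf <- bundle$truth$families[[id]]
    if (!identical(sort(rownames(f$msa)), tf$taxa))
      stop2("verify_scenario(): presence mismatch for ", id)
    if (f$type == "orfan" && nrow(f$msa) != 1L)
      stop2("verify_scenario(): ORFan ", id, " has ", nrow(f$msa), " members")
  }
  for (rec in bundle$truth$indels) {
    m <- bundle$families[[rec$family]]$msa
    region <- m[, (rec$start + 1L):rec$end, drop = FALSE]
    members <- rownames(m)
    if (rec$type == "insertion") {
      holders <- rec$clade
      gappers <- setdiff(members, holders)
    } else {
      gappers <- rec$clade
      holders <- setdiff(members, gappers)
    }
    if (any(region[match(gappers, members), ] != "-"))
      stop2("verify_scenario(): non-gap in gap side of indel on ", rec$family)
    hcounts <- rowSums(region[match(holders, members), , drop = FALSE] != "-")
    if (min(hcounts) != rec$len_min || max(hcounts) != rec$len_max)
      stop2("verify_scenario(): indel length mismatch on ", rec$family)
    fw <- bundle$config$flank_width
    fl <- m[, c((rec$start - fw + 1L):rec$start,
                (rec$end + 1L):(rec$end + fw)), drop = FALSE]
    if (any(fl == "-") || any(apply(fl, 2L, function(cc) length(unique(cc))) != 1L))
      stop2("verify_scenario(): flank not frozen on ", rec$family)
  }
  if (bundle$config$decoy_rate == 0 && nrow(bundle$hits)) {
    famq <- sub("^[^|]*\\|", "", bundle$hits$query_id)
    fams <- sub("^[^|]*\\|", "", bundle$hits$subject_id)
    if (any(famq != fams))
      stop2("verify_scenario(): cross-family hit at decoy rate 0")
  }
  invisible(TRUE)
}

#' The deep-split bootstrap scenario
#'
#' Two four-taxon groups separated by a long internal branch (total 1.0
#' substitutions/site between group stems against 0.05 pendant edges);
#' `n_genes` families are evolved and concatenated. Used to demonstrate that
#' the planted deep split receives near-unanimous bootstrap support.
#'
#' @param seed integer seed.
#' @param n_genes number of families to concatenate.
#' @param gene_len length of each family (aa).
#' @return a list: `aln` (the concatenated [as_msa()]), `tree` (the generating
#'   tree), `split` (tip labels of one side of the planted deep split).
#' @export
deep_split_scenario <- function(seed = 7L, n_genes = 5L, gene_len = 120L) {
  set.seed(seed)
  nwk <- paste0("((a1:0.05,a2:0.05,a3:0.05,a4:0.05)A:0.5,",
                "(b1:0.05,b2:0.05,b3:0.05,b4:0.05)B:0.5)R;")
  tree <- parse_newick(nwk)
  msas <- lapply(seq_len(n_genes), function(i)
    as_msa(evolve_family(tree, gene_len)$msa))
  names(msas) <- sprintf("g%02d", seq_len(n_genes))
  cc <- concatenate(msas, "strict")
  list(aln = cc$msa, tree = tree, split = paste0("a", 1:4))
}
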