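test_that("evolution follows the stated substitution law", {
  # zero-length branch: child identical to parent
  tr0 <- parse_newick("(A:0,B:0)r;")
  set.seed(1)
  fam <- evolve_family(tr0, 100)
  expect_identical(fam$msa["A", ], fam$msa["B", ])

  # substitution events occur at rate 1 - exp(-t)
  tr <- parse_newick("(A:0.2,B:0)r;")
  set.seed(2)
  fracs <- replicate(50, {
    f <- evolve_family(tr, 300)
    f$n_events / f$n_site_branch
  })
  expect_lt(abs(mean(fracs) * 2 - (1 - exp(-0.2))), 0.02)
  # (factor 2: only the A branch has nonzero length, so the per-site-branch
  # event rate averages the 0.2 branch with the zero branch)

  # saturation: child/parent identity approaches 1/20
  trsat <- parse_newick("(A:10,B:0)r;")
  set.seed(3)
  idents <- replicate(50, {
    f <- evolve_family(trsat, 300)
    mean(f$msa["A", ] == f$msa["B", ])
  })
  expect_lt(abs(mean(idents) - 1 / 20), 0.03)
})

test_that("plant_indel constructs the promised region and frozen flanks", {
  tr <- parse_newick("(((A:.1,B:.1)ab:.1,C:.1)abc:.1,(D:.1,E:.1)de:.1)r;")
  set.seed(5)
  fam <- evolve_family(tr, 80)
  pl <- plant_indel(fam$msa, tr, "ab", 6, flank = 5, type = "insertion")
  m <- pl$msa; t <- pl$truth
  expect_identical(ncol(m), 86L)
  expect_identical(t$end - t$start, 6L)
  region <- m[, (t$start + 1):t$end, drop = FALSE]
  expect_true(all(region[c("A", "B"), ] != "-"))
  expect_true(all(region[c("C", "D", "E"), ] == "-"))
  expect_identical(region["A", ], region["B", ])   # conserved insert
  for (cols in list((t$start - 4):t$start, (t$end + 1):(t$end + 5))) {
    fl <- m[, cols, drop = FALSE]
    expect_true(all(fl != "-"))
    expect_true(all(apply(fl, 2, function(x) length(unique(x))) == 1))
  }
  expect_identical(t$polarity, "insert_in_clade")

  # deletion: carriers lose residues, width unchanged
  pl2 <- plant_indel(fam$msa, tr, "de", 2, flank = 5, type = "deletion")
  expect_identical(ncol(pl2$msa), 80L)
  reg2 <- pl2$msa[, (pl2$truth$start + 1):pl2$truth$end, drop = FALSE]
  expect_true(all(reg2[c("D", "E"), ] == "-"))
  expect_true(all(reg2[c("A", "B", "C"), ] != "-"))
  expect_identical(pl2$truth$polarity, "deletion_in_clade")

  # planting at a leaf gives an ORFan-like private indel
  pl3 <- plant_indel(fam$msa, tr, "C", 3, type = "insertion")
  reg3 <- pl3$msa[, (pl3$truth$start + 1):pl3$truth$end, drop = FALSE]
  expect_true(all(reg3["C", ] != "-"))
  expect_true(all(reg3[c("A", "B", "D", "E"), ] == "-"))

  expect_error(plant_indel(fam$msa[, 1:12], tr, "ab", 6), "too short")
})

test_that("the E-value model reproduces its closed form and decoy contract", {
  tr <- parse_newick("(A:0,B:0)r;")
  set.seed(6)
  fams <- list(list(id = "f1", msa = evolve_family(tr, 100)$msa))
  h <- emit_hit_table(fams, e_model = c(a = 5, b = 100, sigma = 0), rho = 0)
  # identical pair at sigma = 0: E = 10^-(5 + 100) exactly
  expect_equal(h$evalue, rep(1e-105, 2))
  expect_identical(h$pident, rep(100, 2))

  # rho = 0: no row joins two families
  set.seed(7)
  tr2 <- parse_newick("(A:.1,B:.1)r;")
  fams2 <- list(list(id = "f1", msa = evolve_family(tr2, 60)$msa),
                list(id = "f2", msa = evolve_family(tr2, 60)$msa))
  h0 <- emit_hit_table(fams2, rho = 0)
  expect_true(all(sub(".*\\|", "", h0$query_id) ==
                  sub(".*\\|", "", h0$subject_id)))

  # rho = 1: every non-homologous ordered pair gets exactly one decoy
  h1 <- emit_hit_table(fams2, rho = 1)
  decoys <- h1[!h1$homolog, ]
  expect_identical(nrow(decoys), 8L)   # 4 seqs -> 2*2 cross pairs * 2 dirs * 2
  expect_true(all(decoys$evalue >= 1e-4 & decoys$evalue <= 10))
  expect_identical(anyDuplicated(paste(decoys$query_id, decoys$subject_id)), 0L)
})

test_that("generate_scenario is deterministic and internally consistent", {
  cfg <- scenario_config(
    targets = c("CladeA", "LowBA"),
    planted = c(CladeA = 2L, LowBA = 2L),
    n_universal = 3L, n_orfans = 2L, root_len = 120L,
    indels = list(list(family = "U001", node = "CladeC", length = 4L,
                       type = "insertion")),
    seed = 11L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_scenario(cfg, d1)
  b2 <- generate_scenario(cfg, d2)
  expect_true(verify_scenario(b1))
  for (f in c("hits.tsv", "taxonomy.tsv", "clades.tsv", "tree.nwk",
              "queries.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_identical(readLines(file.path(d1, "msas", "U001.afa")),
                   readLines(file.path(d2, "msas", "U001.afa")))

  # truth bookkeeping
  expect_identical(b1$truth$counts$families, 3L + 4L + 2L)
  expect_identical(sum(vapply(b1$truth$families, function(f)
    f$type == "orfan", TRUE)), 2L)
  # written files parse back into the same world
  map <- read_taxonomy_map(file.path(d1, "taxonomy.tsv"))
  expect_identical(map$seq2taxon, b1$map$seq2taxon)
  tr <- parse_newick(file = file.path(d1, "tree.nwk"))
  expect_setequal(tr$tip.label, b1$tree$tip.label)
  hits <- read_hit_table(file.path(d1, "hits.tsv"))
  expect_identical(nrow(hits), nrow(b1$hits))
})

test_that("losses carve subtrees out of planted families", {
  cfg <- scenario_config(
    targets = "CladeC", planted = c(CladeC = 1L), n_universal = 0L,
    n_orfans = 0L, indels = list(),
    losses = list(list(family = "P_CladeC_01", node = "MIT")),
    seed = 3L)
  b <- generate_scenario(cfg)
  pres <- b$truth$families$P_CladeC_01$taxa
  expect_false(any(c("MIT1", "MIT2") %in% pres))
  expect_identical(b$truth$families$P_CladeC_01$n_losses, 1L)
  expect_identical(b$truth$families$P_CladeC_01$loss_nodes, "MIT")
})

test_that("an empty scenario is a valid bundle", {
  cfg <- scenario_config(targets = character(0),
                         planted = setNames(integer(0), character(0)),
                         n_universal = 0L, n_orfans = 0L, indels = list(),
                         seed = 1L)
  b <- generate_scenario(cfg)
  expect_length(b$families, 0)
  expect_identical(nrow(b$hits), 0L)
  expect_identical(nrow(b$queries), 0L)
})
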