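test_that("concatenate appends columns and records partitions", {
  m1 <- random_alignment(5, 10)
  m2 <- random_alignment(5, 15)
  rownames(m2) <- rownames(m1)
  cc <- concatenate(list(g1 = m1, g2 = m2), "strict")
  expect_identical(ncol(cc$msa), 25L)
  expect_identical(cc$partitions$start, c(0L, 10L))
  expect_identical(cc$partitions$end, c(10L, 25L))

  # pad policy fills absent taxa with gaps; strict errors naming the taxon
  m3 <- m2[1:4, , drop = FALSE]
  expect_error(concatenate(list(g1 = m1, g2 = as_msa(m3)), "strict"), "s5")
  cp <- concatenate(list(g1 = m1, g2 = as_msa(m3)), "pad")
  expect_identical(paste0(unclass(cp$msa)["s5", 11:25], collapse = ""),
                   strrep("-", 15))
  expect_error(concatenate(list(g1 = m1, g1 = m1)), "duplicate")
})

test_that("the block filter honours the half-gap rule and trims blocks", {
  # a column gapped in 4/6 sequences is dropped in half mode
  set.seed(40)
  mm <- matrix(rep(sample(cladesig:::AA_LETTERS, 30, TRUE), each = 6),
               nrow = 6, dimnames = list(paste0("s", 1:6), NULL))
  mm[1:4, 15] <- "-"
  fb <- filter_blocks(as_msa(mm))
  expect_false(15 %in% fb$kept)
  expect_setequal(fb$kept, setdiff(1:30, 15))

  # fully conserved ungapped alignment passes through intact
  cons <- as_msa(matrix(rep(sample(cladesig:::AA_LETTERS, 50, TRUE), each = 6),
                        nrow = 6, dimnames = list(paste0("s", 1:6), NULL)))
  fb2 <- filter_blocks(cons)
  expect_identical(fb2$kept, 1:50)

  # a 9-column nonconserved stretch (b3 = 8) is removed, flanking
  # highly conserved blocks are kept
  set.seed(4)
  left <- matrix(rep(sample(cladesig:::AA_LETTERS, 12, TRUE), each = 6), 6)
  right <- matrix(rep(sample(cladesig:::AA_LETTERS, 12, TRUE), each = 6), 6)
  noisy <- replicate(9, sample(c("A", "C", "D", "E", "F", "G"), 6))
  aln <- as_msa(`rownames<-`(cbind(left, noisy, right), paste0("s", 1:6)))
  fb3 <- filter_blocks(aln)
  expect_identical(fb3$kept, c(1:12, 22:33))
})

test_that("block filter invariants hold on random gapped alignments", {
  set.seed(13)
  for (i in 1:10) {
    m <- unclass(random_alignment(6, 80))
    gaps <- sample(length(m), round(0.1 * length(m)))
    m[gaps] <- "-"
    # add some conserved anchor columns
    anchor <- sample(80, 20)
    m[, anchor] <- matrix(m[1, anchor], 6, 20, byrow = TRUE)
    fb <- filter_blocks(as_msa(m))
    expect_true(all(fb$kept %in% seq_len(80)))
    expect_false(is.unsorted(fb$kept))
    if (length(fb$kept)) {
      expect_true(all(colMeans(unclass(fb$msa) == "-") <= 0.5))
      fb2 <- filter_blocks(fb$msa)
      expect_identical(fb2$kept, seq_along(fb$kept))   # idempotence
    }
  }
})

test_that("pairwise Kimura distances follow the closed form and its domain", {
  a <- strrep("A", 10)
  m <- as_msa(c(x = a, y = a))
  expect_identical(pairwise_kimura(m)["x", "y"], 0)

  m2 <- as_msa(c(x = strrep("A", 10), y = paste0(strrep("A", 9), "C")))
  expect_equal(pairwise_kimura(m2)["x", "y"], -log(1 - 0.1 - 0.2 * 0.01),
               tolerance = 1e-12)

  # p = 0.9 is outside the domain: 0.2 p^2 + p - 1 >= 0 at p ~ 0.854
  m3 <- as_msa(c(x = strrep("A", 10), y = paste0("A", strrep("C", 9))))
  expect_error(pairwise_kimura(m3), "domain")

  # gap handling: pairwise deletion excludes gapped sites
  m4 <- as_msa(c(x = "AAAA-AAAAA", y = "AAAAC-AAAA"))
  expect_identical(pairwise_kimura(m4)["x", "y"], 0)
  expect_error(pairwise_kimura(as_msa(c(x = "-A", y = "A-"))),
               "no comparable sites")

  # monotone increasing in p, and d >= p on the domain
  p <- seq(0.05, 0.80, by = 0.05)
  d <- -log(1 - p - 0.2 * p^2)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("neighbour joining recovers the additive quartet with its lengths", {
  labs <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["a", "b"] <- 3; D["a", "c"] <- 5; D["a", "d"] <- 6
  D["b", "c"] <- 6; D["b", "d"] <- 7; D["c", "d"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  truth <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  pend <- function(t) {
    setNames(t$edge.length[match(seq_along(t$tip.label), t$edge[, 2])],
             t$tip.label)
  }
  expect_equal(pend(tr)[labs], c(a = 1, b = 2, c = 3, d = 4),
               tolerance = 1e-12)
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(sum(internal), 1, tolerance = 1e-12)

  # n = 3 closed form
  D3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  expect_equal(sort(t3$edge.length), c(0, 2, 3), tolerance = 1e-12)

  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- NaN
  expect_error(nj_tree(Dn), "NA/NaN")
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ is consistent on additive matrices and matches the ape oracle", {
  set.seed(31)
  for (i in 1:10) {
    tr <- random_tree(sample(5:12, 1))
    D <- ape::cophenetic.phylo(tr)
    D <- D[order(rownames(D)), order(colnames(D))]
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    oracle <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(oracle), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap resamples to full length and is seed-reproducible", {
  set.seed(2)
  tr <- random_tree(6)
  tr$edge.length <- tr$edge.length * 0.3   # keep p inside the Kimura domain
  aln <- as_msa(evolve_family(tr, 200)$msa)
  b1 <- bootstrap_support(aln, n_reps = 25, seed = 99)
  b2 <- bootstrap_support(aln, n_reps = 25, seed = 99)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  # support labels decorate the original topology
  expect_equal(ape::dist.topo(ape::unroot(b1$tree),
                              ape::unroot(nj_tree(pairwise_kimura(aln)))),
               0, ignore_attr = TRUE)
})
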