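test_that("build_presence_matrix handles calls, hits and thresholds", {
  taxa <- c("A", "B", "C")
  # from hits: 1e-5 does not clear the 1e-6 presence bar
  h <- data.frame(query_id = c("f1", "f1", "f1"),
                  taxon_id = c("A", "B", "C"),
                  evalue = c(1e-10, 1e-7, 1e-5))
  pm <- build_presence_matrix(h, taxa, e_presence = 1e-6)
  expect_identical(unname(pm["f1", ]), c(1L, 1L, 0L))

  # empty input
  pm0 <- build_presence_matrix(h[0, ], taxa)
  expect_identical(nrow(pm0), 0L)
  expect_identical(colnames(pm0), taxa)

  # unknown taxon rejected
  expect_error(build_presence_matrix(
    data.frame(query_id = "f", taxon_id = "Z", evalue = 1e-9), taxa),
    "absent from the reference leaf set")
})

test_that("infer_gain_loss places gains and minimal losses", {
  tr <- parse_newick("(((A:1,B:1)ab:1,C:1)abc:1,D:1)root;")
  g1 <- infer_gain_loss(c("A", "B"), tr)
  expect_identical(g1$gain_label, "ab")
  expect_identical(g1$n_losses, 0L)

  g2 <- infer_gain_loss(c("A", "B", "D"), tr)
  expect_identical(g2$gain_label, "root")
  expect_identical(g2$loss_labels, "C")
  expect_identical(g2$n_losses, 1L)

  g3 <- infer_gain_loss(c("A", "B", "C", "D"), tr)
  expect_identical(g3$gain_label, "root")
  expect_identical(g3$n_losses, 0L)

  expect_error(infer_gain_loss(character(0), tr), "all-absent")
  expect_error(infer_gain_loss(c("A", "Z"), tr), "not in tree")
  expect_error(infer_gain_loss("A", ape::unroot(tr)), "rooted")
})

test_that("loss sets satisfy the annotation invariants", {
  set.seed(21)
  for (i in 1:20) {
    tr <- random_tree(sample(5:9, 1))
    present <- sample(tr$tip.label, sample(1:(length(tr$tip.label) - 1), 1))
    g <- infer_gain_loss(present, tr)
    under <- tips_under(tr, g$gain_node)
    expect_true(all(present %in% under))
    lost <- as.character(unlist(lapply(g$loss_branches, tips_under,
                                       tree = tr)))
    # losses partition exactly the absent leaves under the gain node
    expect_setequal(lost, setdiff(under, present))
    expect_identical(anyDuplicated(lost), 0L)
  }
})

test_that("Dollo loss counts match the exhaustive-minimality oracle", {
  set.seed(77)
  for (i in 1:60) {
    tr <- random_tree(sample(4:8, 1))
    k <- sample(seq_len(length(tr$tip.label)), 1)
    present <- sample(tr$tip.label, k)
    fast <- infer_gain_loss(present, tr)
    slow <- bf_dollo(tr, present)
    expect_identical(fast$gain_node, slow$gain)
    expect_identical(fast$n_losses, slow$n_losses)
  }
})

test_that("summarize_gains conserves counts and covers all nodes", {
  tr <- parse_newick("(((A:1,B:1)ab:1,C:1)abc:1,D:1)root;")
  pm <- rbind(f1 = c(A = 1, B = 1, C = 0, D = 0),
              f2 = c(A = 1, B = 1, C = 0, D = 0),
              f3 = c(A = 1, B = 1, C = 1, D = 1))
  gains <- map_gains(pm, tr)
  s <- summarize_gains(gains, tr)
  expect_identical(sum(s), 3L)
  expect_identical(unname(s["ab"]), 2L)
  expect_identical(unname(s["root"]), 1L)
  # empty annotation list: all zeros
  s0 <- summarize_gains(gains[0, ], tr)
  expect_identical(sum(s0), 0L)
  expect_length(s0, length(tr$tip.label) + tr$Nnode)
})

test_that("map_gains flags heavy-loss families as LGT candidates", {
  tr <- parse_newick("((((A:1,B:1):1,C:1):1,(D:1,E:1):1):1,(F:1,G:1):1)r;")
  pm <- rbind(patchy = c(A = 1, B = 0, C = 0, D = 0, E = 0, F = 0, G = 1))
  g <- map_gains(pm, tr, lgt_ratio = 1)
  expect_true(g$lgt_flag[1])
  expect_identical(g$gain_label[1], node_label(tr, length(tr$tip.label) + 1L))
})
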