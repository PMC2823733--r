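# CSI scanner on constructed alignments with planted patterns.

planted_msa <- function() {
  as_msa(c(s1 = "AAAAAQQQCCCCC", s2 = "AAAAAQQQCCCCC", s3 = "AAAAAQQQCCCCC",
           s4 = "AAAAA---CCCCC", s5 = "AAAAA---CCCCC", s6 = "AAAAA---CCCCC"))
}

test_that("read_alignment normalizes and validates FASTA input", {
  m <- read_alignment(text = ">a\nACDEFGHIKL\n>b\nACDEFGHIKW\n>c\nACDEF-HIKL")
  expect_identical(ncol(m), 10L)
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_error(read_alignment(text = ">a\nACDEFGHIKL\n>b\nACDEFGHIK"),
               "unequal.*'b'")
  m2 <- read_alignment(text = ">x\nacd-")
  expect_identical(unname(unclass(m2)[1, ]), c("A", "C", "D", "-"))
  expect_error(as_msa(c(a = "AC.D")), "'\\.'")
})

test_that("a planted insertion is called with exact boundaries and polarity", {
  m <- planted_msa()
  cc <- scan_indels(m, c("s1", "s2", "s3"), outgroup = "s6",
                    params = csi_params(flank_min_identity = 1))
  expect_identical(nrow(cc), 1L)
  expect_identical(cc$start, 5L)
  expect_identical(cc$end, 8L)
  expect_identical(c(cc$len_min, cc$len_max), c(3L, 3L))
  expect_identical(cc$polarity, "insert_in_clade")
  expect_identical(cc$pattern, "A")
})

test_that("swapping gap state between clade and rest flips to a deletion", {
  m <- as_msa(c(s1 = "AAAAA---CCCCC", s2 = "AAAAA---CCCCC",
                s3 = "AAAAA---CCCCC", s4 = "AAAAAQQQCCCCC",
                s5 = "AAAAAQQQCCCCC", s6 = "AAAAAQQQCCCCC"))
  cc <- scan_indels(m, c("s1", "s2", "s3"), outgroup = "s6",
                    params = csi_params(flank_min_identity = 1))
  expect_identical(nrow(cc), 1L)
  expect_identical(cc$polarity, "deletion_in_clade")
  expect_identical(cc$pattern, "B")
  expect_identical(c(cc$start, cc$end), c(5L, 8L))
  # deletion length measured on the residue-holding side
  expect_identical(c(cc$len_min, cc$len_max), c(3L, 3L))
})

test_that("alignments without gap separation yield no calls", {
  m <- as_msa(c(a = "AAAAAQQQCCCCC", b = "AAAAAQQQCCCCC",
                c = "AAAAAWQQCCCCC", d = "AAAAAQQWCCCCC"))
  expect_identical(nrow(scan_indels(m, c("a", "b"), "d", csi_params())), 0L)
})

test_that("degraded flanks reject the call", {
  # left-flank columns have majority fraction 3/6 = 0.5 < 0.6
  m <- as_msa(c(s1 = "ACAACQQQCCCCC", s2 = "ACAACQQQCCCCC",
                s3 = "ACAACQQQCCCCC", s4 = "CACCA---CCCCC",
                s5 = "CACCA---CCCCC", s6 = "CACCA---CCCCC"))
  cc <- scan_indels(m, c("s1", "s2", "s3"), "s6",
                    csi_params(flank_min_identity = 0.6))
  expect_identical(nrow(cc), 0L)
  # the same pattern with conserved flanks is accepted
  cc2 <- scan_indels(planted_msa(), c("s1", "s2", "s3"), "s6",
                     csi_params(flank_min_identity = 0.6))
  expect_identical(nrow(cc2), 1L)
})

test_that("a carrier with an internal gap yields a length range", {
  m <- as_msa(c(s1 = "AAAAAQQQQQCCCCC", s2 = "AAAAAQQ-QQCCCCC",
                s3 = "AAAAAQQQQQCCCCC", s4 = "AAAAA-----CCCCC",
                s5 = "AAAAA-----CCCCC", s6 = "AAAAA-----CCCCC"))
  # tau = 0 splits the region at the gapped column
  cc0 <- scan_indels(m, c("s1", "s2", "s3"), "s6",
                     csi_params(flank_min_identity = 1, tolerance = 0))
  expect_false(any(cc0$start == 5 & cc0$end == 10))
  # sufficient tolerance (> 1/3) recovers the full region with range 4-5
  cc <- scan_indels(m, c("s1", "s2", "s3"), "s6",
                    csi_params(flank_min_identity = 1, tolerance = 0.34))
  expect_identical(nrow(cc), 1L)
  expect_identical(c(cc$start, cc$end), c(5L, 10L))
  expect_identical(c(cc$len_min, cc$len_max), c(4L, 5L))
  expect_identical(cc$supporting, "s1,s2,s3")
})

test_that("regions are maximal and label swap is symmetric", {
  set.seed(9)
  for (i in 1:10) {
    base <- random_alignment(8, 60)
    m <- unclass(base)
    s <- sample(15:40, 1); w <- sample(1:6, 1)
    carriers <- paste0("s", 1:4)
    m[!(rownames(m) %in% carriers), s:(s + w - 1L)] <- "-"
    # freeze flanks so the call survives the conservation check
    m[, (s - 5):(s - 1)] <- matrix(m[1, (s - 5):(s - 1)], 8, 5, byrow = TRUE)
    m[, (s + w):(s + w + 4)] <- matrix(m[1, (s + w):(s + w + 4)], 8, 5,
                                       byrow = TRUE)
    msa <- as_msa(m)
    a <- scan_indels(msa, carriers, character(0),
                     csi_params(flank_min_identity = 0.6))
    b <- scan_indels(msa, setdiff(rownames(m), carriers), character(0),
                     csi_params(flank_min_identity = 0.6))
    # maximality: no adjacent/overlapping regions of the same pattern
    for (cc in list(a, b)) {
      for (p in unique(cc$pattern)) {
        rr <- cc[cc$pattern == p, ]
        if (nrow(rr) >= 2) expect_true(all(diff(rr$start) > 1))
      }
    }
    # symmetry: same regions, patterns swapped
    expect_identical(a[, c("start", "end")], b[, c("start", "end")])
    expect_identical(a$pattern, chartr("AB", "BA", b$pattern))
  }
})

test_that("overlapping clade and outgroup sets error", {
  m <- planted_msa()
  expect_error(scan_indels(m, c("s1", "s2"), c("s2", "s6")), "overlap")
  expect_error(scan_indels(m, rownames(m), character(0)), "non-clade")
})

test_that("render_indel produces a dash-notation block", {
  m <- planted_msa()
  cc <- scan_indels(m, c("s1", "s2", "s3"), "s6",
                    csi_params(flank_min_identity = 1))
  out <- render_indel(m, cc[1, ], flank = 5)
  expect_length(out, 6)
  expect_match(out[1], "AAAAAQQQCCCCC")
  expect_match(out[4], "\\.\\.\\.")   # gaps in non-carriers
})
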