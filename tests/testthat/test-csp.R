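# The CSP decision rules, exercised on constructed hit tables.

test_that("all-in-clade significant hits give specific_core", {
  w <- rule_world()
  ev <- setNames(rep(1e-30, 5), paste0("T", 1:5, "|fam"))
  d <- classify_protein("q1", 300, q1_hits(w, ev), "TargetClade", w$defs)
  expect_identical(d$verdict, "specific_core")
  expect_setequal(d$presence_taxa, paste0("T", 1:5))
  expect_length(d$missing_taxa, 0)
})

test_that("weak foreign hits above the ceiling leave the call specific", {
  w <- rule_world()
  ev <- c(setNames(c(rep(1e-30, 4), 1e-20), paste0("T", 1:5, "|fam")),
          "F1|fam" = 1e-3)
  d <- classify_protein("q1", 300, q1_hits(w, ev), "TargetClade", w$defs)
  expect_identical(d$verdict, "specific_core")
  # gap ratio 1e-3 / 1e-20 = 1e17
  expect_equal(d$gap_ratio, 1e17, tolerance = 1e-6)
  expect_identical(d$foreign_evidence$taxon, "F1")
})

test_that("significant foreign hits disqualify the clean specific verdicts", {
  w <- rule_world()
  base <- setNames(rep(1e-30, 5), paste0("T", 1:5, "|fam"))
  # one isolated foreign taxon: retained with the taxon on record
  d1 <- classify_protein("q1", 300,
                         q1_hits(w, c(base, "F1|fam" = 1e-6)),
                         "TargetClade", w$defs)
  expect_identical(d1$verdict, "retained_with_exception")
  expect_match(paste(d1$notes, collapse = " "), "F1")
  # two distinct foreign taxa: rejected, blocking hit reported
  d2 <- classify_protein("q1", 300,
                         q1_hits(w, c(base, "F1|fam" = 1e-6, "F2|fam" = 1e-8)),
                         "TargetClade", w$defs)
  expect_identical(d2$verdict, "not_specific")
  expect_match(paste(d2$notes, collapse = " "), "F2")
})

test_that("homologs confined to the query's own taxon are ORFan-excluded", {
  w <- rule_world()
  # no hits at all
  d0 <- classify_protein("q1", 300, q1_hits(w, setNames(numeric(0), character(0))),
                         "TargetClade", w$defs)
  expect_identical(d0$verdict, "orfan_excluded")
  # hits only to another protein of the query's own taxon
  d1 <- classify_protein("q1", 300, q1_hits(w, c("T1|fam" = 1e-80)),
                         "TargetClade", w$defs)
  expect_identical(d1$verdict, "orfan_excluded")
})

test_that("missing members map to the asterisk tier then to rejection", {
  taxa <- paste0("M", 1:12)
  map <- taxonomy_map(c(paste0(taxa, "|fam"), "q1"), c(taxa, "M1"))
  defs <- clade_defs(list(Big = taxa), all_taxa = map_taxa(map))
  mk <- function(n_present) {
    ev <- setNames(rep(1e-30, n_present), paste0("M", seq_len(n_present), "|fam"))
    rows <- lapply(names(ev), function(s) hit_row("q1", s, ev[[s]], slen = 300L))
    annotate_hits(do.call(make_hit_table, rows), map, defs = defs)
  }
  expect_identical(
    classify_protein("q1", 300, mk(10), "Big", defs)$verdict,
    "specific_partial")
  expect_identical(
    classify_protein("q1", 300, mk(12), "Big", defs)$verdict,
    "specific_core")
  expect_identical(
    classify_protein("q1", 300, mk(9), "Big", defs)$verdict,
    "not_specific")
})

test_that("whitelisted plastid hits are retained with an exception note", {
  w <- rule_world()
  ev <- c(setNames(rep(1e-30, 5), paste0("T", 1:5, "|fam")), "PL|fam" = 1e-40)
  d <- classify_protein("q1", 300, q1_hits(w, ev), "TargetClade", w$defs)
  expect_identical(d$verdict, "retained_with_exception")
  expect_match(paste(d$notes, collapse = " "), "whitelisted.*PL")
})

test_that("the subject length check gates presence", {
  w <- rule_world()
  rows <- c(lapply(paste0("T", 1:4, "|fam"), function(s)
    hit_row("q1", s, 1e-30, slen = 300L)),
    list(hit_row("q1", "T5|fam", 1e-30, slen = 100L)))  # 100/300 < 0.7
  ann <- annotate_hits(do.call(make_hit_table, rows), w$map, defs = w$defs)
  d <- classify_protein("q1", 300, ann, "TargetClade", w$defs)
  expect_identical(d$verdict, "specific_partial")
  expect_identical(d$missing_taxa, "T5")
  # soft mode keeps it core
  d2 <- classify_protein("q1", 300, ann, "TargetClade", w$defs,
                         csp_params(length_check = "warn"))
  expect_identical(d2$verdict, "specific_core")
})

test_that("thresholds move verdicts only in the allowed direction", {
  w <- rule_world()
  set.seed(5)
  rank_ok <- function(v) v %in% c("specific_core", "specific_partial",
                                  "retained_with_exception")
  for (i in 1:30) {
    present <- sample(2:5, 1)
    ev <- setNames(10^-runif(present, 8, 40),
                   paste0("T", seq_len(present), "|fam"))
    if (runif(1) < 0.7)
      ev <- c(ev, setNames(10^-runif(2, 1, 8), c("F1|fam", "F2|fam")))
    h <- q1_hits(w, ev)
    strict <- classify_protein("q1", 300, h, "TargetClade", w$defs,
                               csp_params(e_sig = 1e-4))
    lax <- classify_protein("q1", 300, h, "TargetClade", w$defs,
                            csp_params(e_sig = 1e-6, e_presence = 1e-6))
    # shrinking the foreign-significance ceiling never turns a specific
    # verdict into a rejection
    if (rank_ok(strict$verdict)) expect_true(lax$verdict != "not_specific")
    # raising gap_factor never creates new specific verdicts
    hi_gap <- classify_protein("q1", 300, h, "TargetClade", w$defs,
                               csp_params(gap_factor = 1e9))
    if (!rank_ok(strict$verdict)) expect_false(rank_ok(hi_gap$verdict))
  }
})

test_that("call_genome assigns the most specific target and is deterministic", {
  taxa <- c("N1", "N2", "O1", "O2", "X1")
  map <- taxonomy_map(c(paste0(taxa, "|f1"), "q1"), c(taxa, "N1"))
  defs <- clade_defs(list(Nostocales = c("N1", "N2"),
                          NOC = c("N1", "N2", "O1", "O2")),
                     all_taxa = map_taxa(map))
  ann <- annotate_hits(make_hit_table(hit_row("q1", "N2|f1", 1e-40, slen = 300L)),
                       map, defs = defs)
  queries <- data.frame(query_id = "q1", length = 300)
  calls <- call_genome(queries, ann, list("NOC", "Nostocales"), defs)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$target, "Nostocales")   # smaller resolved set wins

  # byte-identical output on identical input
  calls2 <- call_genome(queries, ann, list("NOC", "Nostocales"), defs)
  expect_identical(
    serialize(calls, NULL), serialize(calls2, NULL))

  expect_error(call_genome(rbind(queries, queries), ann,
                           list("Nostocales"), defs), "duplicate")
  empty <- annotate_hits(make_hit_table(hit_row("zz", "N2|f1", 1e-40))[0, ],
                         map, defs = defs)
  expect_identical(nrow(call_genome(queries, empty, list("Nostocales"), defs)),
                   0L)
})

test_that("csp_params validates and reads from key=value config", {
  expect_error(csp_params(e_presence = 1e-3), "e_presence")
  expect_error(csp_params(gap_factor = 0.5))
  expect_error(csp_params(min_members = 1))
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# config", "e_sig=1e-5", "gap_factor=100",
               "length_ratio_bounds=0.8,1.2",
               "exception_groups=plastid_eukaryote,algae"), p)
  cfg <- read_csp_config(p)
  expect_identical(cfg$e_sig, 1e-5)
  expect_identical(cfg$length_ratio_bounds, c(0.8, 1.2))
  expect_setequal(cfg$exception_groups, c("plastid_eukaryote", "algae"))
  writeLines("nonsense=1", p)
  expect_error(read_csp_config(p), "unknown key")
})
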