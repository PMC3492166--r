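test_that("gc content is the G+C fraction", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  # validated subgroup assay forward primer: 11 G/C over 20 nt by hand count
  expect_equal(gc_content("CCAGCAACTGCCGCAAATCT"), 0.55)
  expect_error(gc_content("ACGU"), "ACGT")
})

test_that("the bundled hordein primer table parses as valid assays", {
  pr <- hordein_data("primers")
  expect_equal(nrow(pr), 27)
  expect_false(any(grepl("[^ACGT]", c(pr$forward, pr$reverse))))
  lens <- nchar(c(pr$forward, pr$reverse))
  cons <- primer_constraints()  # tolerance on: 17-23 nt
  expect_true(all(lens >= cons$len_lo & lens <= cons$len_hi))
  expect_setequal(unique(pr$level),
                  c("family", "subfamily", "subgroup", "member", "reference"))
})

test_that("candidate enumeration is exhaustive on small templates", {
  set.seed(21)
  tmpl <- rand_seq(300)
  aln1 <- align_group(c(t1 = tmpl))
  cons <- primer_constraints(min_len = 20, max_len = 20, gc_min = 0.3,
                             gc_max = 0.7, amplicon_min = 60,
                             amplicon_max = 90, tolerance = FALSE)
  cands <- enumerate_candidates(aln1, "t1", cons)
  expect_gt(nrow(cands), 0)
  expect_true(all(cands$amplicon_len >= 60 & cands$amplicon_len <= 90))

  # two identical targets give exactly the single-target candidate list
  aln2 <- align_group(c(t1 = tmpl, t2 = tmpl))
  cands2 <- enumerate_candidates(aln2, c("t1", "t2"), cons)
  expect_equal(cands2, cands)

  # full agreement with the brute-force oracle at a smaller scale
  set.seed(22)
  small <- rand_seq(80)
  cons_s <- primer_constraints(min_len = 8, max_len = 10, gc_min = 0,
                               gc_max = 1, amplicon_min = 25,
                               amplicon_max = 45, tolerance = FALSE)
  got <- enumerate_candidates(align_group(c(s = small)), "s", cons_s)
  want <- brute_candidates(small, 8:10, 25, 45)
  key <- function(d) {
    with(d, sort(paste(fwd_start, fwd_len, rev_start, rev_len, forward, reverse)))
  }
  expect_equal(key(got), key(want))
})

test_that("reverse primers are reverse complements of sense windows", {
  set.seed(23)
  tmpl <- rand_seq(200)
  cands <- enumerate_candidates(
    align_group(c(t = tmpl)), "t",
    primer_constraints(min_len = 18, max_len = 18, gc_min = 0, gc_max = 1,
                       amplicon_min = 60, amplicon_max = 80,
                       tolerance = FALSE))
  i <- 1
  sense <- substr(tmpl, cands$rev_start[i] + 1,
                  cands$rev_start[i] + cands$rev_len[i])
  expect_equal(cands$reverse[i], revcomp(sense))
})

test_that("discriminating columns are found and scored at the 3' terminus", {
  set.seed(25)
  base <- rand_seq(240)
  # non-target differs from the two (identical) targets at exactly two
  # columns, ~80 bp apart
  nt <- base
  p1 <- 80L; p2 <- 160L
  for (pos in c(p1, p2)) {
    substr(nt, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                    substr(nt, pos, pos))[1]
  }
  aln <- align_group(c(t1 = base, t2 = base, n1 = nt))
  cons <- primer_constraints(min_len = 18, max_len = 18, gc_min = 0,
                             gc_max = 1, amplicon_min = 100,
                             amplicon_max = 130, tolerance = FALSE)
  cands <- enumerate_candidates(aln, c("t1", "t2"), cons)
  expect_gt(nrow(cands), 0)

  # a pair with forward 3' end on the first SNP and reverse 3' end on the
  # second discriminates with both primers
  hit <- cands[cands$fwd_start + cands$fwd_len == p1 & cands$rev_start == p2 - 1, ]
  expect_gt(nrow(hit), 0)
  sc <- discrimination_score(hit[1, ], aln, "n1", cons)
  expect_false(sc$rejected)
  expect_equal(sc$terminal_discrimination, 2)

  # a pair whose 3'-exact zones avoid both discriminating columns binds
  # the non-target perfectly enough to amplify it: rejected
  fe <- cands$fwd_start + cands$fwd_len
  sel <- !(p1 >= fe - 2 & p1 <= fe) &
    !((p2 - 1) >= cands$rev_start & (p2 - 1) <= cands$rev_start + 2)
  far <- cands[sel, ]
  expect_gt(nrow(far), 0)
  sc2 <- discrimination_score(far[1, ], aln, "n1", cons)
  expect_true(sc2$rejected)
})

test_that("dimer screening flags 3'-anchored complementarity", {
  f <- "ACGTCAGGACTGACCTGATC"
  expect_false(isTRUE(dimer_screen(f, revcomp(f))))
  expect_true(isTRUE(dimer_screen("AAAAAAAAAA", "AAAAAAAAAA")))

  # engineered 4-base 3' cross-complement at threshold 4, cross-checked by
  # the independent suffix/reverse-complement scan
  fwd <- "CCATAAGGATTCAAGGGTCA"
  rev_ <- "GGATTACCTTAAGGCTTGAC"  # suffix TGAC; revcomp(TGAC) = GTCA
  run <- brute_tail_complement(fwd, rev_)
  expect_gte(run, 4)
  res <- dimer_screen(fwd, rev_, max_3prime_complement = 4)
  expect_false(isTRUE(res))
  expect_equal(attr(res, "run"),
               max(run, brute_tail_complement(fwd, fwd),
                   brute_tail_complement(rev_, rev_)))
})

test_that("hierarchical design resolves synthetic panels with unique SNPs", {
  fx <- design_fixture()
  des <- fx$design
  # family, both subfamilies, and all six members resolved
  expect_equal(nrow(des$sets), 9)
  expect_equal(nrow(des$unresolved), 0)
  expect_setequal(unique(des$sets$level), c("family", "subfamily", "member"))
  # deterministic replay
  des2 <- design_hierarchy(fx$classification, fx$aln, fx$fam$panel)
  expect_identical(des2$sets, des$sets)
})

test_that("identical sequences admit only a family-common set", {
  set.seed(27)
  tmpl <- rand_seq(400)
  panel <- tiny_panel(c(m1 = tmpl, m2 = tmpl, m3 = tmpl))
  aln <- align_group(panel$sequences)
  cl <- cut_subfamilies(build_tree(aln), mode = "k_groups", value = 1)
  des <- design_hierarchy(cl, aln, panel)
  expect_equal(des$sets$level, "family")
  expect_equal(sort(des$unresolved$name), c("m1", "m2", "m3"))
})

test_that("members differing only in repeat copy number are unresolvable", {
  set.seed(28)
  flank1 <- rand_seq(220)
  flank2 <- rand_seq(260)
  block <- function(n) strrep("CCTCAACAACTA", n)
  panel <- tiny_panel(c(m1 = paste0(flank1, block(5), flank2),
                        m2 = paste0(flank1, block(9), flank2)))
  trimmed <- trim_cores(panel)
  # cores are identical once the repeat block is gone
  expect_equal(unname(trimmed$panel$sequences[["m1"]]),
               unname(trimmed$panel$sequences[["m2"]]))
  aln <- align_group(trimmed$panel$sequences)
  cl <- cut_subfamilies(build_tree(aln), mode = "k_groups", value = 2)
  des <- design_hierarchy(cl, aln, panel)
  expect_true(all(des$sets$level == "family"))
  expect_setequal(des$unresolved$name, c("m1", "m2"))
})
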