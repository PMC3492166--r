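test_that("binding site finder agrees with brute force on random templates", {
  set.seed(31)
  tmpl <- rand_seq(1000)
  rules <- binding_rules(three_prime_exact = 3, max_total_mismatch = 2)

  perfect <- substr(tmpl, 101, 120)
  mm3 <- perfect
  substr(mm3, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(mm3, 20, 20))[1]
  mm_int <- perfect
  for (pos in c(5, 11)) {
    substr(mm_int, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                        substr(mm_int, pos, pos))[1]
  }
  mm_many <- perfect
  for (pos in c(5, 9, 13)) {
    substr(mm_many, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                         substr(mm_many, pos, pos))[1]
  }
  rev_perfect <- revcomp(substr(tmpl, 501, 520))

  # exact substring is found at its position
  hit <- find_binding_sites(perfect, tmpl, rules, "+")
  expect_true(100 %in% hit$start)
  # a 3'-terminal mismatch kills the otherwise perfect site
  expect_false(100 %in% find_binding_sites(mm3, tmpl, rules, "+")$start)
  # internal mismatches within budget keep it
  h2 <- find_binding_sites(mm_int, tmpl, rules, "+")
  expect_true(100 %in% h2$start)
  expect_equal(h2$mismatches[h2$start == 100], 2)
  # three mismatches exceed the budget
  expect_false(100 %in% find_binding_sites(mm_many, tmpl, rules, "+")$start)
  # reverse-strand site
  expect_true(500 %in% find_binding_sites(rev_perfect, tmpl, rules, "-")$start)

  # exhaustive agreement, both strands, several primers
  for (p in list(perfect, mm3, mm_int, mm_many, rev_perfect)) {
    for (strand in c("+", "-")) {
      got <- find_binding_sites(p, tmpl, rules, strand)
      want <- brute_binding_sites(p, tmpl, 3, 2, strand)
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("binding is strand-symmetric under template reverse complement", {
  set.seed(32)
  tmpl <- rand_seq(600)
  L <- nchar(tmpl)
  rules <- binding_rules(3, 2)
  p <- substr(tmpl, 201, 220)
  f <- find_binding_sites(p, tmpl, rules, "+")
  r <- find_binding_sites(p, revcomp(tmpl), rules, "-")
  expect_setequal(L - f$end, r$start)
  expect_setequal(L - f$start, r$end)
})

test_that("amplicon prediction pairs forward with downstream reverse sites", {
  set.seed(33)
  tmpl <- rand_seq(400)
  f <- substr(tmpl, 101, 120)
  r <- revcomp(substr(tmpl, 181, 200))
  amp <- predict_amplicons(f, r, tmpl)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$fwd_start, 100)
  expect_equal(amp$rev_end, 200)
  expect_equal(amp$product_length, 100)

  # forward site without a reverse partner: nothing
  set.seed(34)
  expect_equal(nrow(predict_amplicons(f, revcomp(rand_seq(20)), tmpl)), 0)

  # two forward sites and one reverse site within range: two products,
  # matching the cartesian enumeration of site combinations
  fw_site <- substr(tmpl, 1, 20)
  tmpl2 <- paste0(fw_site, rand_seq(40), fw_site, rand_seq(40),
                  substr(tmpl, 181, 200), rand_seq(30))
  amp2 <- predict_amplicons(fw_site, r, tmpl2, max_product = 1000)
  f_sites <- brute_binding_sites(fw_site, tmpl2, 3, 2, "+")$start
  r_sites <- brute_binding_sites(r, tmpl2, 3, 2, "-")$start
  combos <- expand.grid(fs = f_sites, rs = r_sites)
  combos <- combos[combos$rs >= combos$fs + 20, ]
  expect_equal(nrow(amp2), nrow(combos))
  expect_equal(nrow(amp2), 2)
  expect_setequal(amp2$fwd_start, combos$fs)

  # max_product bound excludes distant pairings
  expect_equal(nrow(predict_amplicons(fw_site, r, tmpl2, max_product = 60)), 0)
})

test_that("specificity verdicts cover specific, family-wide and silent cases", {
  fx <- design_fixture()
  panel <- fx$fam$panel
  sets <- fx$design$sets

  fam_set <- as.list(sets[sets$level == "family", ][1, ])
  rep_fam <- validate_specificity(fam_set, panel)
  expect_equal(rep_fam$verdict, "specific")
  expect_setequal(rep_fam$amplified_ids, names(panel$sequences))

  mem_set <- as.list(sets[sets$level == "member", ][1, ])
  rep_mem <- validate_specificity(mem_set, panel)
  expect_equal(rep_mem$verdict, "specific")
  expect_equal(rep_mem$amplified_ids, mem_set$target_ids)

  # primers from a different sequence universe are silent
  set.seed(35)
  foreign <- list(name = "foreign", forward = rand_seq(20),
                  reverse = rand_seq(20),
                  target_ids = names(panel$sequences)[1])
  expect_equal(validate_specificity(foreign, panel)$verdict, "silent")
})

test_that("loosening the mismatch budget only grows the amplified set", {
  fx <- design_fixture()
  panel <- fx$fam$panel
  sets <- fx$design$sets
  for (i in seq_len(nrow(sets))) {
    prev <- character(0)
    for (mm in 0:4) {
      rules <- binding_rules(three_prime_exact = 1, max_total_mismatch = mm)
      amp <- validate_specificity(as.list(sets[i, ]), panel, rules)$amplified_ids
      expect_true(all(prev %in% amp))
      prev <- amp
    }
  }
})

test_that("pooled mixtures round-trip exactly at zero noise and add up", {
  fx <- design_fixture()
  panel <- fx$fam$panel
  sets <- fx$design$sets
  curve <- standard_curve(-3.9, 5.2)  # deliberately non-canonical curve
  added <- stats::setNames(c(1.2, 0.8, 0.5, 0.3, 0.9, 0.6),
                           names(panel$sequences))
  pm <- pooled_mixture_experiment(panel, added, sets, curve)
  expect_equal(pm$calculated_amol, pm$added_amol, tolerance = 1e-9)
  expect_equal(pm$calculated_sd, rep(0, nrow(pm)))

  # family-common amount equals the sum over its disjoint subfamily sets
  fam_amt <- pm$calculated_amol[pm$primer_set == "Common_SYN"]
  sub_amt <- pm$calculated_amol[pm$primer_set %in% c("G1", "G2")]
  expect_equal(fam_amt, sum(sub_amt), tolerance = 1e-9)

  # tiny template amounts push Ct beyond the reliable window and get flagged
  tiny <- stats::setNames(rep(1e-9, 6), names(panel$sequences))
  pm_tiny <- pooled_mixture_experiment(panel, tiny, sets[1, , drop = FALSE],
                                       curve)
  expect_true(pm_tiny$ct_flagged[1])
})

test_that("noisy pooled recovery is unbiased within Monte-Carlo error", {
  fx <- design_fixture()
  panel <- fx$fam$panel
  fam_set <- fx$design$sets[fx$design$sets$level == "family", ][1, , drop = FALSE]
  curve <- standard_curve(-3.3219, 4.0)
  added <- stats::setNames(rep(0.5, 6), names(panel$sequences))
  set.seed(2024)
  pm <- pooled_mixture_experiment(panel, added, fam_set, curve,
                                  noise_sd_ct = 0.1, n_replicates = 100)
  se <- pm$calculated_sd / sqrt(100)
  expect_lt(abs(pm$calculated_amol - pm$added_amol), 2 * se + 0.01 * pm$added_amol)
})
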