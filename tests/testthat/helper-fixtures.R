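# shared synthetic-family design fixture, computed once per test run
.fixture_env <- new.env(parent = emptyenv())

design_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  spec <- synthetic_family_spec(n_subfamilies = 2, members_per_subfamily = 3,
                                seed = 7)
  fam <- generate_family(spec)
  trimmed <- trim_cores(fam$panel)
  aln <- align_group(trimmed$panel$sequences)
  tree <- build_tree(aln)
  cl <- cut_subfamilies(tree, mode = "k_groups", value = 2)
  des <- design_hierarchy(cl, aln, fam$panel)
  .fixture_env$fx <- list(fam = fam, trimmed = trimmed, aln = aln,
                          tree = tree, classification = cl, design = des)
  .fixture_env$fx
}

# tiny single-family panel from explicit sequences
tiny_panel <- function(seqs, family = "X") {
  allele_panel(seqs, data.frame(id = names(seqs), family = family,
                                stringsAsFactors = FALSE))
}
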