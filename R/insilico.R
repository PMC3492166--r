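#' Primer-binding rules for in-silico amplification
#'
#' The binding model is deliberately simple and conservative: a primer is
#' said to bind where it aligns ungapped with at most `max_total_mismatch`
#' mismatches and its 3'-terminal `three_prime_exact` bases match exactly.
#' The 3' requirement encodes the single-base discrimination principle a
#' proof-reading polymerase gives allele-specific assays: a mismatch at the
#' extending end blocks product formation, whereas 5' mismatches are
#' tolerated. Amplification is binary; no efficiency penalty is modelled
#' for internal mismatches.
#'
#' @param three_prime_exact Number of terminal 3' bases that must match
#'   exactly (>= 1; default 3, a conservative amplification call).
#' @param max_total_mismatch Maximum mismatches across the whole footprint
#'   (default 2).
#' @param min_primer_template_identity Optional additional floor on
#'   footprint identity (fraction; default 0 = inactive).
#' @return Object of class `binding_rules`.
#' @export
binding_rules <- function(three_prime_exact = 3L, max_total_mismatch = 2L,
                          min_primer_template_identity = 0) {
  stopifnot(three_prime_exact >= 1, max_total_mismatch >= 0,
            min_primer_template_identity >= 0,
            min_primer_template_identity <= 1)
  structure(
    list(three_prime_exact = as.integer(three_prime_exact),
         max_total_mismatch = as.integer(max_total_mismatch),
         min_primer_template_identity = min_primer_template_identity),
    class = "binding_rules"
  )
}

#' Reverse complement of a nucleotide string
#'
#' @param x Nucleotide string (ACGTN).
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Find primer-binding sites on a template
#'
#' Slides the primer (forward strand) or its reverse complement (reverse
#' strand) along the template and reports every position satisfying the
#' [binding_rules()]. `N` in the template mismatches every primer base.
#' For a reverse-strand primer the 3' terminus maps to the left (smallest
#' coordinate) end of the footprint, and the exact-match window is applied
#' there.
#'
#' @param primer Primer 5'->3' (ACGT only).
#' @param template Template string (sense strand).
#' @param rules A `binding_rules` object.
#' @param strand `"+"` (primer anneals to the antisense strand, extends
#'   rightward on the sense coordinates) or `"-"` (primer anneals to the
#'   sense strand).
#' @return Data frame with `start`, `end` (0-based half-open footprint on
#'   the sense strand), `strand` and `mismatches`; zero rows when no site
#'   qualifies.
#' @export
find_binding_sites <- function(primer, template, rules = binding_rules(),
                               strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(inherits(rules, "binding_rules"))
  if (grepl("[^ACGT]", primer)) stop("primer must be ACGT only")
  k <- nchar(primer)
  L <- nchar(template)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (k > L || k < rules$three_prime_exact) return(empty)
  probe <- if (strand == "+") primer else revcomp(primer)
  p <- strsplit(probe, "")[[1]]
  tchars <- strsplit(template, "")[[1]]
  n_pos <- L - k + 1L
  mm <- integer(n_pos)
  mm3 <- integer(n_pos)
  t3 <- rules$three_prime_exact
  # on the sense-strand window, the primer's 3'-terminal bases sit at the
  # right end for "+" and at the left end for "-"
  three_prime_idx <- if (strand == "+") seq(k - t3 + 1L, k) else seq_len(t3)
  for (j in seq_len(k)) {
    neq <- tchars[j:(j + n_pos - 1L)] != p[j]
    mm <- mm + neq
    if (j %in% three_prime_idx) mm3 <- mm3 + neq
  }
  keep <- mm <= rules$max_total_mismatch & mm3 == 0L &
    (1 - mm / k) >= rules$min_primer_template_identity
  if (!any(keep)) return(empty)
  idx <- which(keep)
  data.frame(start = idx - 1L, end = idx - 1L + k,
             strand = strand, mismatches = mm[idx],
             stringsAsFactors = FALSE)
}

#' Predict amplicons of a primer pair on one template
#'
#' Pairs every forward binding site with every downstream, non-overlapping
#' reverse site within `max_product`. The default `max_product` of 1000 bp
#' is an off-target scanning bound; the 50-150 bp amplicon constraint
#' applies at design time only.
#'
#' @param forward,reverse Primer strings 5'->3'.
#' @param template Template string (sense strand).
#' @param rules A `binding_rules` object.
#' @param max_product Maximum product length in bp.
#' @return Data frame with `fwd_start`, `rev_end` (0-based half-open
#'   product interval), `product_length`, `fwd_mismatches`,
#'   `rev_mismatches`; zero rows when nothing amplifies.
#' @export
predict_amplicons <- function(forward, reverse, template,
                              rules = binding_rules(), max_product = 1000L) {
  f <- find_binding_sites(forward, template, rules, "+")
  r <- find_binding_sites(reverse, template, rules, "-")
  out <- data.frame(fwd_start = integer(0), rev_end = integer(0),
                    product_length = integer(0), fwd_mismatches = integer(0),
                    rev_mismatches = integer(0), stringsAsFactors = FALSE)
  if (nrow(f) == 0 || nrow(r) == 0) return(out)
  for (i in seq_len(nrow(f))) {
    ok <- r$start >= f$end[i] & (r$end - f$start[i]) <= max_product
    if (any(ok)) {
      out <- rbind(out, data.frame(
        fwd_start = f$start[i], rev_end = r$end[ok],
        product_length = r$end[ok] - f$start[i],
        fwd_mismatches = f$mismatches[i], rev_mismatches = r$mismatches[ok],
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Validate primer-set specificity against a panel
#'
#' Replays the wet-lab validation in silico: the primer set is applied to
#' every panel member and the set of amplified members is compared with the
#' intended targets. A set is `specific` when it amplifies exactly its
#' (non-empty) target set, `silent` when nothing amplifies, and
#' `nonspecific` otherwise.
#'
#' @param primer_set List or one-row data frame with elements `name`,
#'   `forward`, `reverse` and `target_ids` (character vector, or a
#'   comma-separated string).
#' @param panel An `allele_panel`.
#' @param rules A `binding_rules` object.
#' @param max_product Maximum product length for the off-target scan.
#' @return Object of class `specificity_report`: list with `name`,
#'   `target_ids`, `amplified_ids`, `verdict` and `amplicons` (per-member
#'   prediction list).
#' @export
validate_specificity <- function(primer_set, panel, rules = binding_rules(),
                                 max_product = 1000L) {
  stopifnot(inherits(panel, "allele_panel"))
  targets <- primer_set$target_ids
  if (length(targets) == 1 && grepl(",", targets)) {
    targets <- strsplit(targets, ",")[[1]]
  }
  targets <- trimws(unlist(targets))
  if (!all(targets %in% names(panel$sequences))) {
    stop("target ids not in panel: ",
         paste(setdiff(targets, names(panel$sequences)), collapse = ", "))
  }
  amps <- lapply(panel$sequences, function(s) {
    predict_amplicons(primer_set$forward, primer_set$reverse, s, rules,
                      max_product)
  })
  amplified <- names(amps)[vapply(amps, nrow, integer(1)) > 0]
  verdict <- if (length(amplified) == 0) {
    "silent"
  } else if (setequal(amplified, targets)) {
    "specific"
  } else {
    "nonspecific"
  }
  structure(
    list(name = primer_set$name, target_ids = targets,
         amplified_ids = amplified, verdict = verdict, amplicons = amps),
    class = "specificity_report"
  )
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity_report '%s': %s\n", x$name, x$verdict))
  cat("  targets  :", paste(x$target_ids, collapse = ", "), "\n")
  cat("  amplified:", paste(x$amplified_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Simulated pooled-clone validation experiment
#'
#' Emulates the experiment in which equal panels of cloned templates are
#' pooled at known concentrations and each primer set's signal is read off
#' the standard curve: the effective template for a set is the sum of the
#' added amounts over the clones it amplifies, the corresponding Ct is
#' simulated through the curve's forward map (optionally with Gaussian Ct
#' noise), and the amount is then recovered through the quantification
#' path (Ct -> mass -> moles). At zero noise the recovery is exact, and
#' amounts measured by subfamily sets add up to the family-common amount
#' whenever their clone subsets partition the family.
#'
#' @param panel An `allele_panel` of the pooled clones.
#' @param added_amol Named numeric vector: attomoles per microliter added
#'   for each panel member.
#' @param primer_sets Data frame with columns `name`, `forward`, `reverse`,
#'   `target_ids` (comma-separated), as produced by [design_hierarchy()].
#' @param curve A `standard_curve`.
#' @param rules A `binding_rules` object.
#' @param noise_sd_ct Gaussian SD added to simulated Ct values (default 0).
#' @param n_replicates Simulated replicate count (default 3).
#' @param mass_model `"ds"` or `"ss"`; see [ng_to_amol()].
#' @return Data frame with one row per primer set: `primer_set`,
#'   `added_amol`, `calculated_amol`, `calculated_sd`, `mean_ct`,
#'   `ct_flagged` (outside the curve's reliable window), `n_amplified`.
#' @export
pooled_mixture_experiment <- function(panel, added_amol, primer_sets,
                                      curve, rules = binding_rules(),
                                      noise_sd_ct = 0, n_replicates = 3L,
                                      mass_model = c("ds", "ss")) {
  stopifnot(inherits(panel, "allele_panel"), inherits(curve, "standard_curve"))
  mass_model <- match.arg(mass_model)
  ids <- names(panel$sequences)
  if (!all(ids %in% names(added_amol))) {
    stop("added_amol must name every panel member")
  }
  lens <- stats::setNames(panel$meta$coding_length_bp, panel$meta$id)
  rows <- vector("list", nrow(primer_sets))
  for (i in seq_len(nrow(primer_sets))) {
    ps <- as.list(primer_sets[i, ])
    rep_ <- validate_specificity(ps, panel, rules)
    amp <- rep_$amplified_ids
    added <- sum(added_amol[amp])
    if (length(amp) == 0 || added <= 0) {
      rows[[i]] <- data.frame(
        primer_set = ps$name, added_amol = added, calculated_amol = 0,
        calculated_sd = 0, mean_ct = NA_real_, ct_flagged = FALSE,
        n_amplified = length(amp), stringsAsFactors = FALSE
      )
      next
    }
    basis_len <- mean(lens[amp])
    ng <- amol_to_ng(added, basis_len, mass_model)
    ct <- predict(curve, ng) +
      if (noise_sd_ct > 0) stats::rnorm(n_replicates, 0, noise_sd_ct) else
        rep(0, n_replicates)
    rec_ng <- ct_to_concentration(curve, ct, flag_window = FALSE)
    rec <- ng_to_amol(rec_ng, basis_len, mass_model)
    rows[[i]] <- data.frame(
      primer_set = ps$name, added_amol = added,
      calculated_amol = mean(rec), calculated_sd = stats::sd(rec),
      mean_ct = mean(ct),
      ct_flagged = mean(ct) < curve$ct_min || mean(ct) > curve$ct_max,
      n_amplified = length(amp), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
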