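#' Primer design constraints
#'
#' Default design space: 18-22 nt oligonucleotides with 40-60% GC and a
#' predicted amplicon of 50-150 bp, the ranges suited to SYBR Green assays
#' on storage-protein coding sequences. With `tolerance = TRUE` (default)
#' the length bound is relaxed by 1 nt and the GC bound by 5 percentage
#' points on each side, since hand-curated assays for these families
#' routinely include 17-mers or 23-mers marginally outside the nominal
#' window; `tolerance = FALSE` enforces the strict bounds.
#'
#' @param min_len,max_len Primer length bounds (nt).
#' @param gc_min,gc_max GC-content bounds (fractions).
#' @param amplicon_min,amplicon_max Product length bounds (bp).
#' @param three_prime_protect Number of 3'-terminal bases used by the
#'   discrimination score (default 1: a single terminal mismatch is already
#'   destabilizing).
#' @param tolerance Apply the +-1 nt / +-5% GC relaxation (default `TRUE`).
#' @return Object of class `primer_constraints` with effective bounds
#'   `len_lo`, `len_hi`, `gc_lo`, `gc_hi` precomputed.
#' @export
primer_constraints <- function(min_len = 18L, max_len = 22L,
                               gc_min = 0.40, gc_max = 0.60,
                               amplicon_min = 50L, amplicon_max = 150L,
                               three_prime_protect = 1L,
                               tolerance = TRUE) {
  stopifnot(min_len <= max_len, amplicon_min <= amplicon_max,
            gc_min <= gc_max, three_prime_protect >= 1)
  tol_len <- if (tolerance) 1L else 0L
  tol_gc <- if (tolerance) 0.05 else 0
  structure(
    list(min_len = as.integer(min_len), max_len = as.integer(max_len),
         gc_min = gc_min, gc_max = gc_max,
         amplicon_min = as.integer(amplicon_min),
         amplicon_max = as.integer(amplicon_max),
         three_prime_protect = as.integer(three_prime_protect),
         tolerance = isTRUE(tolerance),
         len_lo = as.integer(min_len) - tol_len,
         len_hi = as.integer(max_len) + tol_len,
         gc_lo = gc_min - tol_gc, gc_hi = gc_max + tol_gc),
    class = "primer_constraints"
  )
}

#' GC content of an oligonucleotide
#'
#' @param primer Non-empty ACGT string.
#' @return `(#G + #C) / length`, a fraction.
#' @export
gc_content <- function(primer) {
  stopifnot(nchar(primer) > 0)
  if (grepl("[^ACGT]", primer)) stop("primer must be ACGT only")
  chars <- strsplit(primer, "")[[1]]
  mean(chars %in% c("G", "C"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-primer windows on the alignment: identical and gap/N-free across
# all target rows, length and GC within the (effective) constraint bounds.
# Returns list(win = data.frame(start0, len, seq), pruned = named counts,
# ungapped = per-target cumulative ungapped coordinate per column).
.candidate_windows <- function(alignment, targets, constraints) {
  rows <- alignment$rows[targets]
  mat <- do.call(rbind, strsplit(rows, ""))
  ncol_aln <- ncol(mat)
  consensus_ok <- apply(mat, 2, function(col) {
    length(unique(col)) == 1L && col[1] != "-" && col[1] != "N"
  })
  ref <- mat[1, ]
  ungapped <- lapply(targets, function(id) {
    cumsum(strsplit(alignment$rows[[id]], "")[[1]] != "-")
  })
  names(ungapped) <- targets

  pruned <- c(consensus = 0L, gc = 0L, amplicon = 0L)
  windows <- list()
  run_ok <- cumsum(c(0L, as.integer(consensus_ok)))
  for (len in seq(constraints$len_lo, constraints$len_hi)) {
    if (len > ncol_aln) next
    starts <- seq_len(ncol_aln - len + 1L)
    all_ok <- (run_ok[starts + len] - run_ok[starts]) == len
    pruned["consensus"] <- pruned["consensus"] + sum(!all_ok)
    starts <- starts[all_ok]
    if (!length(starts)) next
    seqs <- vapply(starts, function(s) paste(ref[s:(s + len - 1L)], collapse = ""),
                   character(1))
    gc <- vapply(seqs, gc_content, numeric(1))
    gc_ok <- gc >= constraints$gc_lo & gc <= constraints$gc_hi
    pruned["gc"] <- pruned["gc"] + sum(!gc_ok)
    if (!any(gc_ok)) next
    windows[[length(windows) + 1L]] <- data.frame(
      start0 = starts[gc_ok] - 1L, len = len, seq = unname(seqs[gc_ok]),
      stringsAsFactors = FALSE
    )
  }
  win <- if (length(windows)) {
    w <- do.call(rbind, windows)
    w <- w[order(w$start0, w$len), , drop = FALSE]
    rownames(w) <- NULL
    w
  } else {
    data.frame(start0 = integer(0), len = integer(0), seq = character(0),
               stringsAsFactors = FALSE)
  }
  n_gap_cols <- sum(!vapply(seq_len(ncol_aln),
                            function(j) all(mat[, j] != "-"), logical(1)))
  list(win = win, pruned = pruned, ungapped = ungapped,
       n_gap_cols = n_gap_cols)
}

# ungapped product length per target for a (fwd window, rev window) pair
.pair_product_lengths <- function(ungapped, targets, fs0, rev_end1) {
  vapply(targets, function(id) {
    u <- ungapped[[id]]
    u[rev_end1] - if (fs0 > 0) u[fs0] else 0L
  }, numeric(1))
}

#' Enumerate candidate primer pairs on a group alignment
#'
#' Scans the alignment for windows that are identical (and gap-free) across
#' all target rows -- degenerate bases are never emitted -- and pairs every
#' qualifying forward window with every downstream, non-overlapping reverse
#' window whose predicted product length is within bounds on every target.
#' The reverse primer is the reverse complement of its sense-strand window.
#'
#' Exhaustive by construction; intended for desk-scale alignments. The
#' bounded search inside [design_hierarchy()] uses the same window
#' enumeration.
#'
#' @param alignment A `group_alignment` covering the candidate targets.
#' @param targets Character vector of target ids (subset of
#'   `alignment$ids`).
#' @param constraints A `primer_constraints` object.
#' @return Data frame of candidates: `forward`, `reverse`, `fwd_start`,
#'   `fwd_len`, `rev_start`, `rev_len` (alignment columns, 0-based),
#'   `amplicon_len` (bp on the first target). When empty, the attribute
#'   `"diagnostic"` names the constraint that pruned the most windows.
#' @export
enumerate_candidates <- function(alignment, targets,
                                 constraints = primer_constraints()) {
  stopifnot(inherits(alignment, "group_alignment"),
            inherits(constraints, "primer_constraints"))
  if (!all(targets %in% alignment$ids)) {
    stop("targets not in alignment: ",
         paste(setdiff(targets, alignment$ids), collapse = ", "))
  }
  cw <- .candidate_windows(alignment, targets, constraints)
  win <- cw$win
  empty <- data.frame(forward = character(0), reverse = character(0),
                      fwd_start = integer(0), fwd_len = integer(0),
                      rev_start = integer(0), rev_len = integer(0),
                      amplicon_len = integer(0), stringsAsFactors = FALSE)
  pruned <- cw$pruned
  if (!nrow(win)) {
    attr(empty, "diagnostic") <- names(which.max(pruned))
    return(empty)
  }
  # alignment-span prefilter: a product of <= amplicon_max ungapped bases
  # spans at most amplicon_max + (gap columns) alignment columns
  span_max <- constraints$amplicon_max + cw$n_gap_cols
  out <- list()
  for (i in seq_len(nrow(win))) {
    fs <- win$start0[i]; fl <- win$len[i]
    cand <- win[win$start0 >= fs + fl &
                  (win$start0 + win$len) - fs <= span_max, , drop = FALSE]
    if (!nrow(cand)) next
    keep <- logical(nrow(cand))
    amp1 <- integer(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      lens <- .pair_product_lengths(cw$ungapped, targets, fs,
                                    cand$start0[j] + cand$len[j])
      ok <- all(lens >= constraints$amplicon_min &
                  lens <= constraints$amplicon_max)
      if (!ok) pruned["amplicon"] <- pruned["amplicon"] + 1L
      keep[j] <- ok
      amp1[j] <- lens[1]
    }
    cand <- cand[keep, , drop = FALSE]
    amp1 <- amp1[keep]
    if (!nrow(cand)) next
    out[[length(out) + 1L]] <- data.frame(
      forward = win$seq[i],
      reverse = vapply(cand$seq, revcomp, character(1), USE.NAMES = FALSE),
      fwd_start = fs, fwd_len = fl,
      rev_start = cand$start0, rev_len = cand$len,
      amplicon_len = amp1, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    attr(empty, "diagnostic") <- names(which.max(pruned))
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-window statistics against each non-target alignment row; column j of
# each matrix corresponds to window j. Gap and N count as mismatches.
.window_stats <- function(win, alignment, nontargets, constraints, rules) {
  nw <- nrow(win)
  nnt <- length(nontargets)
  stats <- list(
    mm_total = matrix(0L, nnt, nw), term_right = matrix(FALSE, nnt, nw),
    term_left = matrix(FALSE, nnt, nw), mm3_right = matrix(0L, nnt, nw),
    mm3_left = matrix(0L, nnt, nw), prot_right = matrix(0L, nnt, nw),
    prot_left = matrix(0L, nnt, nw)
  )
  if (nnt == 0 || nw == 0) return(stats)
  t3 <- rules$three_prime_exact
  prot <- constraints$three_prime_protect
  nt_chars <- lapply(nontargets, function(id) strsplit(alignment$rows[[id]], "")[[1]])
  for (j in seq_len(nw)) {
    idx <- seq(win$start0[j] + 1L, win$start0[j] + win$len[j])
    wchars <- strsplit(win$seq[j], "")[[1]]
    for (n in seq_len(nnt)) {
      rowc <- nt_chars[[n]][idx]
      mm <- rowc != wchars | rowc == "-" | rowc == "N"
      k <- length(mm)
      stats$mm_total[n, j] <- sum(mm)
      stats$term_right[n, j] <- mm[k]
      stats$term_left[n, j] <- mm[1]
      stats$mm3_right[n, j] <- sum(mm[seq(max(1L, k - t3 + 1L), k)])
      stats$mm3_left[n, j] <- sum(mm[seq_len(min(t3, k))])
      stats$prot_right[n, j] <- sum(mm[seq(max(1L, k - prot + 1L), k)])
      stats$prot_left[n, j] <- sum(mm[seq_len(min(prot, k))])
    }
  }
  stats
}

#' Score a candidate pair's power to discriminate targets from non-targets
#'
#' Ranks candidates by (a) how many of the two primers carry a 3'-terminal
#' base that mismatches *every* non-target at the homologous position (0-2;
#' the strongest design has both primers unique to the desired amplicon),
#' then (b) the total number of mismatches against non-targets within the
#' 3'-protect window, then (c) closeness of the amplicon length to the
#' midpoint of the allowed range. A candidate predicted to amplify any
#' non-target under the binding rules (assessed at the homologous site on
#' the alignment) is rejected outright.
#'
#' @param candidate One-row data frame (or list) from
#'   [enumerate_candidates()].
#' @param alignment The `group_alignment` the candidate was designed on.
#' @param nontargets Character vector of non-target ids present in the
#'   alignment (may be empty, e.g. for a family-level set with no
#'   within-panel outgroup).
#' @param constraints A `primer_constraints` object.
#' @param rules A `binding_rules` object.
#' @return List with `rejected` (logical), `terminal_discrimination` (0-2),
#'   `protect_mismatches`, `amplicon_centering` and `score` (numeric vector
#'   for ordering: higher is better in each component).
#' @export
discrimination_score <- function(candidate, alignment, nontargets,
                                 constraints = primer_constraints(),
                                 rules = binding_rules()) {
  stopifnot(inherits(alignment, "group_alignment"))
  fwd_win <- data.frame(start0 = candidate$fwd_start, len = candidate$fwd_len,
                        seq = candidate$forward, stringsAsFactors = FALSE)
  rev_win <- data.frame(start0 = candidate$rev_start, len = candidate$rev_len,
                        seq = revcomp(candidate$reverse),
                        stringsAsFactors = FALSE)
  sf <- .window_stats(fwd_win, alignment, nontargets, constraints, rules)
  sr <- .window_stats(rev_win, alignment, nontargets, constraints, rules)
  nnt <- length(nontargets)
  if (nnt) {
    f_binds <- sf$mm_total[, 1] <= rules$max_total_mismatch & sf$mm3_right[, 1] == 0L
    r_binds <- sr$mm_total[, 1] <= rules$max_total_mismatch & sr$mm3_left[, 1] == 0L
    rejected <- any(f_binds & r_binds)
    terminal <- sum(all(sf$term_right[, 1]), all(sr$term_left[, 1]))
    prot_mm <- sum(sf$prot_right[, 1]) + sum(sr$prot_left[, 1])
  } else {
    rejected <- FALSE; terminal <- 0L; prot_mm <- 0L
  }
  mid <- (constraints$amplicon_min + constraints$amplicon_max) / 2
  centering <- -abs(candidate$amplicon_len - mid)
  list(rejected = rejected, terminal_discrimination = terminal,
       protect_mismatches = prot_mm, amplicon_centering = centering,
       score = c(terminal, prot_mm, centering))
}

#' Screen a primer pair for 3'-anchored dimer formation
#'
#' In-silico surrogate for the no-template control: fails a pair when the
#' 3'-terminal bases of one primer can anneal antiparallel to the
#' 3'-terminal bases of the other (or of itself) over at least
#' `max_3prime_complement` bases, i.e. when the length-`k` suffix of one
#' primer equals the reverse complement of the length-`k` suffix of the
#' other for some `k >= max_3prime_complement`.
#'
#' @param forward,reverse Primer strings 5'->3'.
#' @param max_3prime_complement Complementarity run at or above which the
#'   pair fails (default 4).
#' @return `TRUE` (pass) or `FALSE` (fail), with attribute `"run"` giving
#'   the longest 3'-anchored complementarity run found.
#' @export
dimer_screen <- function(forward, reverse, max_3prime_complement = 4L) {
  tail_run <- function(p, q) {
    # suffix_k(p) == revcomp(suffix_k(q))  <=>  suffix_k(p) == prefix_k(revcomp(q))
    rcq <- revcomp(q)
    kmax <- min(nchar(p), nchar(q))
    run <- 0L
    for (k in seq_len(kmax)) {
      if (substr(p, nchar(p) - k + 1L, nchar(p)) == substr(rcq, 1L, k)) run <- k
    }
    run
  }
  worst <- max(tail_run(forward, reverse),
               tail_run(forward, forward),
               tail_run(reverse, reverse))
  structure(worst < max_3prime_complement, run = worst)
}

# bounded best-pair search for one hierarchy node: scores single windows
# against the non-targets, pairs the most discriminating forward and
# reverse windows under the amplicon constraint, and returns candidate
# pairs in score order (same ordering as discrimination_score, same
# deterministic tie-break)
.design_node <- function(cw, alignment, targets, nontargets, constraints,
                         rules, pool_size = 80L, pairs_per_fwd = 25L) {
  win <- cw$win
  if (!nrow(win)) return(NULL)
  nnt <- length(nontargets)
  if (nnt) {
    # windows are consensus slices of the first target row, so per-column
    # mismatch vectors against each non-target row give every window
    # statistic by cumulative sums
    ref <- strsplit(alignment$rows[[targets[1]]], "")[[1]]
    t3 <- rules$three_prime_exact
    prot <- constraints$three_prime_protect
    s <- win$start0; l <- win$len
    per_nt <- lapply(nontargets, function(id) {
      row <- strsplit(alignment$rows[[id]], "")[[1]]
      mmvec <- row != ref | row == "-" | row == "N"
      cum0 <- c(0L, cumsum(mmvec))
      list(
        mm_total = cum0[s + l + 1L] - cum0[s + 1L],
        term_right = mmvec[s + l], term_left = mmvec[s + 1L],
        mm3_right = cum0[s + l + 1L] - cum0[pmax(s + l - t3, s) + 1L],
        mm3_left = cum0[pmin(s + t3, s + l) + 1L] - cum0[s + 1L],
        prot_right = cum0[s + l + 1L] - cum0[pmax(s + l - prot, s) + 1L],
        prot_left = cum0[pmin(s + prot, s + l) + 1L] - cum0[s + 1L]
      )
    })
    g <- function(field) do.call(rbind, lapply(per_nt, `[[`, field))
    mm_total <- g("mm_total")
    f_binds <- mm_total <= rules$max_total_mismatch & g("mm3_right") == 0L
    r_binds <- mm_total <= rules$max_total_mismatch & g("mm3_left") == 0L
    f_disc <- apply(g("term_right"), 2, all)
    r_disc <- apply(g("term_left"), 2, all)
    f_prot <- colSums(g("prot_right"))
    r_prot <- colSums(g("prot_left"))
  } else {
    f_binds <- r_binds <- matrix(FALSE, 0, nrow(win))
    f_disc <- r_disc <- rep(FALSE, nrow(win))
    f_prot <- r_prot <- rep(0L, nrow(win))
  }
  ord_f <- order(-as.integer(f_disc), -f_prot, win$start0, win$len)
  ord_r <- order(-as.integer(r_disc), -r_prot, win$start0, win$len)
  f_pool <- utils::head(ord_f, pool_size)
  r_rank <- integer(nrow(win)); r_rank[ord_r] <- seq_len(nrow(win))
  span_max <- constraints$amplicon_max + cw$n_gap_cols

  mid <- (constraints$amplicon_min + constraints$amplicon_max) / 2
  # per-target ungapped coordinates of window ends/starts, for vectorized
  # product lengths
  U <- vapply(targets, function(id) {
    cw$ungapped[[id]][win$start0 + win$len]
  }, numeric(nrow(win)))
  S <- vapply(targets, function(id) {
    u <- cw$ungapped[[id]]
    ifelse(win$start0 > 0, u[pmax(win$start0, 1L)], 0)
  }, numeric(nrow(win)))
  if (nrow(win) == 1L) { U <- matrix(U, 1); S <- matrix(S, 1) }
  fwd_idx <- rev_idx <- amp <- integer(0)
  for (i in f_pool) {
    fs <- win$start0[i]; fl <- win$len[i]
    j_all <- which(win$start0 >= fs + fl &
                     (win$start0 + win$len) - fs <= span_max)
    if (!length(j_all)) next
    j_all <- j_all[order(r_rank[j_all])]
    taken <- 0L
    for (j in j_all) {
      lens <- U[j, ] - S[i, ]
      if (any(lens < constraints$amplicon_min |
                lens > constraints$amplicon_max)) next
      if (nnt && any(f_binds[, i] & r_binds[, j])) next
      fwd_idx <- c(fwd_idx, i); rev_idx <- c(rev_idx, j)
      amp <- c(amp, lens[1])
      taken <- taken + 1L
      if (taken >= pairs_per_fwd) break
    }
  }
  if (!length(fwd_idx)) return(NULL)
  p <- data.frame(
    fwd_idx = fwd_idx, rev_idx = rev_idx,
    terminal = as.integer(f_disc[fwd_idx]) + as.integer(r_disc[rev_idx]),
    prot = f_prot[fwd_idx] + r_prot[rev_idx],
    centering = -abs(amp - mid), amplicon_len = amp
  )
  p[order(-p$terminal, -p$prot, -p$centering,
          win$start0[p$fwd_idx], p$amplicon_len), , drop = FALSE]
}

#' Design a hierarchy of discriminating primer sets
#'
#' Attempts one primer set per node of the classification hierarchy: the
#' whole family, each subfamily, and each individual member. For each node,
#' windows identical across the node's members are enumerated on the family
#' alignment, the most discriminating forward and reverse windows (by
#' 3'-terminal mismatch against every non-target, then total 3'-protect
#' mismatches) are paired under the amplicon constraint, pairs predicted to
#' amplify a non-target or failing the [dimer_screen()] are discarded, and
#' the best-ranked survivors are verified by full in-silico PCR against
#' every panel member ([validate_specificity()]); the first fully specific
#' pair is emitted. Nodes for which no compliant set exists are reported as
#' unresolved rather than failing -- members that differ only inside the
#' trimmed-out repeat region are genuinely indistinguishable by this assay.
#'
#' Output is deterministic for a fixed panel and constraints (stable
#' ordering; ties broken by smallest forward start, then shortest
#' amplicon).
#'
#' @param classification A `family_classification` of the panel members.
#' @param alignment A `group_alignment` over the same members (typically of
#'   core sequences).
#' @param panel The `allele_panel` of full sequences used for in-silico
#'   validation.
#' @param constraints A `primer_constraints` object.
#' @param rules A `binding_rules` object.
#' @param max_candidates_checked Cap on how many top-ranked pairs are run
#'   through full in-silico validation per node (default 5).
#' @return List of class `primer_design` with `sets` (data frame: `name`,
#'   `level`, `forward`, `reverse`, `target_ids` comma-separated,
#'   `fwd_start`, `rev_start`, `amplicon_len`, `terminal_discrimination`)
#'   and `unresolved` (data frame: `name`, `level`, `reason`).
#' @export
design_hierarchy <- function(classification, alignment, panel,
                             constraints = primer_constraints(),
                             rules = binding_rules(),
                             max_candidates_checked = 5L) {
  stopifnot(inherits(classification, "family_classification"),
            inherits(alignment, "group_alignment"),
            inherits(panel, "allele_panel"))
  members <- alignment$ids
  fam_label <- unique(panel$meta$family[panel$meta$id %in% members])
  nodes <- list(list(name = paste0("Common_", paste(fam_label, collapse = "+")),
                     level = "family", targets = members))
  for (g in names(classification$groups)) {
    ids <- classification$groups[[g]]
    # singleton subfamilies are reported under their member's own name
    if (length(ids) < length(members) && length(ids) > 1) {
      nodes[[length(nodes) + 1L]] <- list(name = g, level = "subfamily",
                                          targets = ids)
    }
  }
  for (id in members) {
    nodes[[length(nodes) + 1L]] <- list(name = id, level = "member",
                                        targets = id)
  }
  seen <- character(0)  # drop duplicate membership sets (size-1 subfamily = its member)
  sets <- list(); unresolved <- list()
  val_panel <- subset_panel(panel, members)
  for (node in nodes) {
    key <- paste(sort(node$targets), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    nontargets <- setdiff(members, node$targets)
    cw <- .candidate_windows(alignment, node$targets, constraints)
    if (!nrow(cw$win)) {
      unresolved[[length(unresolved) + 1L]] <- data.frame(
        name = node$name, level = node$level,
        reason = paste0("no candidate windows (limiting constraint: ",
                        names(which.max(cw$pruned)), ")"),
        stringsAsFactors = FALSE
      )
      next
    }
    ranked <- .design_node(cw, alignment, node$targets, nontargets,
                           constraints, rules)
    if (is.null(ranked)) {
      unresolved[[length(unresolved) + 1L]] <- data.frame(
        name = node$name, level = node$level,
        reason = "all candidate pairs amplify a non-target or violate the amplicon bound",
        stringsAsFactors = FALSE
      )
      next
    }
    chosen <- NULL
    checked <- 0L
    for (r in seq_len(nrow(ranked))) {
      if (checked >= max_candidates_checked) break
      fi <- ranked$fwd_idx[r]; ri <- ranked$rev_idx[r]
      fwd <- cw$win$seq[fi]
      rev <- revcomp(cw$win$seq[ri])
      if (!isTRUE(dimer_screen(fwd, rev))) next
      checked <- checked + 1L
      ps <- list(name = node$name, forward = fwd, reverse = rev,
                 target_ids = node$targets)
      rep_ <- validate_specificity(ps, val_panel, rules)
      if (rep_$verdict == "specific") {
        chosen <- c(ps, list(
          fwd_start = cw$win$start0[fi], rev_start = cw$win$start0[ri],
          amplicon_len = ranked$amplicon_len[r],
          terminal_discrimination = ranked$terminal[r]
        ))
        break
      }
    }
    if (is.null(chosen)) {
      unresolved[[length(unresolved) + 1L]] <- data.frame(
        name = node$name, level = node$level,
        reason = "no candidate passed dimer screen and full in-silico specificity",
        stringsAsFactors = FALSE
      )
    } else {
      sets[[length(sets) + 1L]] <- data.frame(
        name = chosen$name, level = node$level,
        forward = chosen$forward, reverse = chosen$reverse,
        target_ids = paste(chosen$target_ids, collapse = ","),
        fwd_start = chosen$fwd_start, rev_start = chosen$rev_start,
        amplicon_len = chosen$amplicon_len,
        terminal_discrimination = chosen$terminal_discrimination,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      sets = if (length(sets)) do.call(rbind, sets) else
        data.frame(name = character(0), level = character(0),
                   forward = character(0), reverse = character(0),
                   target_ids = character(0), stringsAsFactors = FALSE),
      unresolved = if (length(unresolved)) do.call(rbind, unresolved) else
        data.frame(name = character(0), level = character(0),
                   reason = character(0), stringsAsFactors = FALSE)
    ),
    class = "primer_design"
  )
}

#' @export
print.primer_design <- function(x, ...) {
  cat("primer_design:", nrow(x$sets), "set(s),",
      nrow(x$unresolved), "unresolved node(s)\n")
  if (nrow(x$sets)) print(x$sets[, c("name", "level", "forward", "reverse")])
  invisible(x)
}
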