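#' Specification of a synthetic homologous gene family
#'
#' Describes a simulated multigene family that mimics the architecture of
#' cereal storage-protein genes: conserved flanks surrounding a central
#' tandem-repeat block, with high sequence identity among members. Members
#' of a subfamily descend from a common founder; founders descend from one
#' ancestor. Divergence is introduced as random substitutions, so within-
#' subfamily identity exceeds between-subfamily identity in expectation.
#'
#' Defaults emulate a hordein-like family: a ~900 bp scaffold, a 12-nt
#' proline/glutamine-codon-rich repeat motif present in 18-28 tandem copies
#' (a 216-336 bp block placed at 45% of the scaffold, so both flanks can
#' carry primers but the downstream flank is reproducibly the longer,
#' trim-surviving one), 10% divergence between subfamilies and 2% within,
#' which puts pairwise identities in the mid-80s to high-90s percent range
#' typical of these families. Each flank additionally carries one conserved
#' segment (`conserved_block_bp`) where divergence is suppressed, mirroring
#' the conserved terminal domains of real storage-protein genes that make
#' family-common primers possible in the first place.
#'
#' @param n_subfamilies Number of subfamilies (>= 1).
#' @param members_per_subfamily Members per subfamily (>= 1).
#' @param ancestor_length_bp Length of the non-repetitive scaffold (both
#'   flanks together), before the repeat block is inserted.
#' @param repeat_motif Repeat unit (ACGT only).
#' @param repeat_copy_range Integer pair: inclusive range of tandem copy
#'   numbers; each member draws its own copy number, so members differ in
#'   length the way real repeat-bearing alleles do.
#' @param between_subfamily_divergence,within_subfamily_divergence Per-site
#'   substitution probabilities applied founder-from-ancestor and
#'   member-from-founder respectively; both in `[0, 1)` and
#'   `between > within` is required when both are positive.
#' @param conserved_block_bp Length of the conserved segment placed in the
#'   middle of each flank (no divergence substitutions there); 0 disables.
#' @param plant_member_snps If `TRUE` (default), each member receives two
#'   reserved private substitutions (one per flank, outside the conserved
#'   segments) that no other member carries, guaranteeing a member-unique
#'   discrimination site for primer design.
#' @param seed Integer seed; the generated panel is byte-identical for a
#'   fixed spec.
#' @return An object of class `synthetic_family_spec` (a validated list).
#' @export
synthetic_family_spec <- function(n_subfamilies = 3,
                                  members_per_subfamily = 3,
                                  ancestor_length_bp = 900,
                                  repeat_motif = "CCACAACAACCT",
                                  repeat_copy_range = c(18L, 28L),
                                  between_subfamily_divergence = 0.10,
                                  within_subfamily_divergence = 0.02,
                                  conserved_block_bp = 150L,
                                  plant_member_snps = TRUE,
                                  seed = 1L) {
  stopifnot(
    n_subfamilies >= 1, members_per_subfamily >= 1,
    ancestor_length_bp >= 100,
    length(repeat_copy_range) == 2, repeat_copy_range[1] >= 1,
    repeat_copy_range[1] <= repeat_copy_range[2],
    between_subfamily_divergence >= 0, between_subfamily_divergence < 1,
    within_subfamily_divergence >= 0, within_subfamily_divergence < 1,
    conserved_block_bp >= 0
  )
  if (grepl("[^ACGT]", repeat_motif)) {
    stop("repeat_motif must contain only A, C, G, T")
  }
  if (between_subfamily_divergence > 0 &&
      between_subfamily_divergence <= within_subfamily_divergence) {
    stop("between_subfamily_divergence must exceed within_subfamily_divergence")
  }
  structure(
    list(
      n_subfamilies = as.integer(n_subfamilies),
      members_per_subfamily = as.integer(members_per_subfamily),
      ancestor_length_bp = as.integer(ancestor_length_bp),
      repeat_motif = repeat_motif,
      repeat_copy_range = as.integer(repeat_copy_range),
      between_subfamily_divergence = between_subfamily_divergence,
      within_subfamily_divergence = within_subfamily_divergence,
      conserved_block_bp = as.integer(conserved_block_bp),
      plant_member_snps = isTRUE(plant_member_snps),
      seed = as.integer(seed)
    ),
    class = "synthetic_family_spec"
  )
}

# substitute positions of a base vector at rate `rate`, avoiding `reserved`
.mutate_sites <- function(bases, rate, reserved = integer(0)) {
  if (rate <= 0) return(bases)
  eligible <- setdiff(seq_along(bases), reserved)
  hit <- eligible[stats::runif(length(eligible)) < rate]
  if (length(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  bases
}

#' Generate a synthetic homologous gene family
#'
#' Simulates the family described by a [synthetic_family_spec()] and returns
#' it as an [allele_panel()] plus ground truth: the true subfamily of every
#' member, the coordinates of the planted repeat block, and the positions of
#' any member-unique substitutions. Truth labels make the generator usable
#' as an oracle for the classification, trimming and primer-design steps.
#'
#' @param spec A `synthetic_family_spec`.
#' @param family_label Family label stored in the panel metadata.
#' @return A list of class `synthetic_family` with elements `panel`
#'   (an `allele_panel`; metadata carries the true subfamily), `truth`
#'   (data frame: `id`, `subfamily`, `repeat_start`, `repeat_end` 0-based
#'   half-open on the member sequence, `repeat_copies`, `snp_left`,
#'   `snp_right` 0-based positions on the member sequence or `NA`) and
#'   `spec`.
#' @export
generate_family <- function(spec, family_label = "SYN") {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n_mem <- spec$n_subfamilies * spec$members_per_subfamily
  L <- spec$ancestor_length_bp
  # repeat block at 45% of the scaffold: both flanks usable for primers,
  # and the downstream flank is reproducibly the longer one, so repeat
  # trimming keeps the same flank for every member
  insert_at <- as.integer(floor(L * 0.45))
  ancestor <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  # conserved segment in the middle of each flank: no divergence there
  cons <- min(spec$conserved_block_bp, insert_at - 60L, L - insert_at - 60L)
  conserved_idx <- integer(0)
  if (cons > 0) {
    s_l <- (insert_at - cons) %/% 2L
    s_r <- insert_at + (L - insert_at - cons) %/% 2L
    conserved_idx <- c(seq(s_l + 1L, s_l + cons), seq(s_r + 1L, s_r + cons))
  }

  # reserve two private SNP positions per member, one per flank, away from
  # the scaffold ends and outside the conserved segments
  snp_reserved <- integer(0)
  snp_left <- snp_right <- rep(NA_integer_, n_mem)
  if (spec$plant_member_snps) {
    left_pool <- setdiff(seq(30L, insert_at - 30L), conserved_idx)
    right_pool <- setdiff(seq(insert_at + 30L, L - 30L), conserved_idx)
    if (length(left_pool) < n_mem || length(right_pool) < n_mem) {
      stop("ancestor_length_bp too small to reserve member-unique sites")
    }
    snp_left <- sample(left_pool, n_mem)
    snp_right <- sample(right_pool, n_mem)
    snp_reserved <- c(snp_left, snp_right)
  }
  reserved <- c(snp_reserved, conserved_idx)

  ids <- character(n_mem)
  seqs <- character(n_mem)
  subfam <- character(n_mem)
  rep_start <- rep_end <- rep_copies <- integer(n_mem)
  motif <- spec$repeat_motif

  m <- 0L
  for (sf in seq_len(spec$n_subfamilies)) {
    founder <- .mutate_sites(ancestor, spec$between_subfamily_divergence, reserved)
    for (k in seq_len(spec$members_per_subfamily)) {
      m <- m + 1L
      bases <- .mutate_sites(founder, spec$within_subfamily_divergence, reserved)
      if (spec$plant_member_snps) {
        for (pos in c(snp_left[m], snp_right[m])) {
          bases[pos] <- sample(setdiff(c("A", "C", "G", "T"), ancestor[pos]), 1L)
        }
      }
      copies <- if (spec$repeat_copy_range[1] == spec$repeat_copy_range[2]) {
        spec$repeat_copy_range[1]
      } else {
        sample(seq(spec$repeat_copy_range[1], spec$repeat_copy_range[2]), 1L)
      }
      block <- strrep(motif, copies)
      seqs[m] <- paste0(
        paste(bases[seq_len(insert_at)], collapse = ""),
        block,
        paste(bases[seq(insert_at + 1L, L)], collapse = "")
      )
      ids[m] <- sprintf("SF%d_M%d", sf, k)
      subfam[m] <- sprintf("SF%d", sf)
      rep_start[m] <- insert_at
      rep_end[m] <- insert_at + nchar(block)
      rep_copies[m] <- copies
    }
  }
  names(seqs) <- ids

  truth <- data.frame(
    id = ids, subfamily = subfam,
    repeat_start = rep_start, repeat_end = rep_end, repeat_copies = rep_copies,
    snp_left = if (spec$plant_member_snps) snp_left - 1L else NA_integer_,
    snp_right = if (spec$plant_member_snps) {
      # right-flank position shifts by the member's own repeat block length
      snp_right - 1L - insert_at + rep_end
    } else NA_integer_,
    stringsAsFactors = FALSE
  )
  meta <- data.frame(
    id = ids, accession = "", cultivar = "synthetic",
    family = family_label, subfamily = subfam, stringsAsFactors = FALSE
  )
  structure(
    list(panel = allele_panel(seqs, meta), truth = truth, spec = spec),
    class = "synthetic_family"
  )
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("synthetic_family:", nrow(x$truth), "members,",
      x$spec$n_subfamilies, "subfamilies (seed", paste0(x$spec$seed, ")\n"))
  invisible(x)
}
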