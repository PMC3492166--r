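#' Detect exact tandem repeats in a nucleotide sequence
#'
#' Scans motif lengths from `min_motif` to `max_motif` (shortest first) and
#' reports every maximal run of at least `min_copies` exact consecutive
#' copies. Runs of a shorter motif take precedence: a candidate interval
#' that overlaps an already-reported interval is skipped, so a homopolymer
#' is reported once with its 1-nt motif (when `min_motif = 1`) rather than
#' again as a 2-nt or 3-nt repeat. Maximality means the run cannot be
#' extended by another full copy on either side; partial flanking copies are
#' not included.
#'
#' The default motif range 2-12 covers the short codon-level repeat units
#' typical of storage-protein genes; imperfect (degenerate) repeats are out
#' of scope.
#'
#' @param sequence Nucleotide string (uppercase ACGTN).
#' @param min_motif,max_motif Inclusive motif length range.
#' @param min_copies Minimum number of exact consecutive copies.
#' @return An object of class `repeat_annotation`: list with `intervals`,
#'   a data frame of `start`, `end` (0-based half-open), `motif`, `copies`,
#'   sorted and non-overlapping; zero rows when nothing qualifies.
#' @export
find_tandem_repeats <- function(sequence, min_motif = 2L, max_motif = 12L,
                                min_copies = 3L) {
  stopifnot(min_motif >= 1, min_motif <= max_motif, min_copies >= 2)
  L <- nchar(sequence)
  iv <- data.frame(start = integer(0), end = integer(0),
                   motif = character(0), copies = integer(0),
                   stringsAsFactors = FALSE)
  if (L < min_motif * min_copies) {
    return(structure(list(intervals = iv), class = "repeat_annotation"))
  }
  covered <- logical(L)
  for (m in seq(min_motif, min(max_motif, L %/% min_copies))) {
    i <- 1L
    while (i + m * min_copies - 1L <= L) {
      motif <- substr(sequence, i, i + m - 1L)
      # count consecutive exact copies starting at i
      c_n <- 1L
      while (i + (c_n + 1L) * m - 1L <= L &&
             substr(sequence, i + c_n * m, i + (c_n + 1L) * m - 1L) == motif) {
        c_n <- c_n + 1L
      }
      if (c_n >= min_copies) {
        # left-maximality: a run found by left-to-right scan could still be
        # preceded by a full copy if we jumped over it; check explicitly
        if (i - m >= 1L && substr(sequence, i - m, i - 1L) == motif) {
          i <- i + 1L
          next
        }
        s0 <- i - 1L
        e0 <- s0 + c_n * m
        i <- i + c_n * m
        # shorter motifs reported earlier take precedence: shed whole
        # copies that overlap already-covered positions, keep the rest
        k_n <- c_n
        while (k_n > 0L && any(covered[(s0 + 1L):(s0 + m)])) {
          s0 <- s0 + m; k_n <- k_n - 1L
        }
        while (k_n > 0L && any(covered[(e0 - m + 1L):e0])) {
          e0 <- e0 - m; k_n <- k_n - 1L
        }
        if (k_n >= min_copies && !any(covered[(s0 + 1L):e0])) {
          iv <- rbind(iv, data.frame(start = s0, end = e0, motif = motif,
                                     copies = k_n, stringsAsFactors = FALSE))
          covered[(s0 + 1L):e0] <- TRUE
        }
      } else {
        i <- i + 1L
      }
    }
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  structure(list(intervals = iv), class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat("repeat_annotation:", nrow(x$intervals), "interval(s)\n")
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Extract the low-repeat core of a sequence
#'
#' Picks the longest contiguous window whose repeat coverage (fraction of
#' positions inside annotated tandem-repeat intervals) does not exceed
#' `threshold`, mirroring the manual "alignment trimming" step in which most
#' of the repetitive region of each allele is cut away before alignment and
#' primer design. Candidate window boundaries are restricted to repeat
#' interval boundaries and the sequence ends, so a run of unannotated
#' positions is never split. Ties on length are broken leftmost.
#'
#' @param sequence Nucleotide string.
#' @param annotation A `repeat_annotation` for this sequence (from
#'   [find_tandem_repeats()]).
#' @param threshold Maximum tolerated repeat coverage of the core window
#'   (default 0.1).
#' @return An object of class `core_region`: list with `start`, `end`
#'   (0-based half-open on the input), `core_sequence`, `repeat_fraction`
#'   (coverage inside the core), `fraction_removed` (share of annotated
#'   positions excluded from the core) and `full_sequence_fallback`
#'   (`TRUE` when no window met the threshold and the full sequence was
#'   returned with a warning).
#' @export
extract_core <- function(sequence, annotation, threshold = 0.1) {
  stopifnot(inherits(annotation, "repeat_annotation"),
            threshold >= 0, threshold <= 1)
  L <- nchar(sequence)
  iv <- annotation$intervals
  if (nrow(iv) && (min(iv$start) < 0 || max(iv$end) > L)) {
    stop("annotation intervals outside sequence bounds")
  }
  covered <- logical(L)
  for (r in seq_len(nrow(iv))) covered[(iv$start[r] + 1L):iv$end[r]] <- TRUE
  cum <- c(0L, cumsum(covered))
  bounds <- sort(unique(c(0L, L, iv$start, iv$end)))
  best <- NULL
  for (a in bounds) {
    for (b in bounds[bounds > a]) {
      cov <- (cum[b + 1L] - cum[a + 1L]) / (b - a)
      if (cov <= threshold) {
        if (is.null(best) || (b - a) > (best$end - best$start)) {
          best <- list(start = a, end = b, cov = cov)
        }
      }
    }
  }
  if (is.null(best)) {
    warning("no window satisfies the repeat-coverage threshold; returning full sequence")
    best <- list(start = 0L, end = L, cov = sum(covered) / L)
    fallback <- TRUE
  } else {
    fallback <- FALSE
  }
  in_core <- sum(covered[seq(best$start + 1L, best$end)])
  total_rep <- sum(covered)
  structure(
    list(
      start = best$start, end = best$end,
      core_sequence = substr(sequence, best$start + 1L, best$end),
      repeat_fraction = best$cov,
      fraction_removed = if (total_rep > 0) 1 - in_core / total_rep else 0,
      full_sequence_fallback = fallback
    ),
    class = "core_region"
  )
}

#' @export
print.core_region <- function(x, ...) {
  cat(sprintf("core_region: [%d, %d) length %d, repeat coverage %.3f\n",
              x$start, x$end, x$end - x$start, x$repeat_fraction))
  invisible(x)
}

#' Trim every panel member to its low-repeat core
#'
#' Convenience wrapper: runs [find_tandem_repeats()] and [extract_core()]
#' on each record of a panel and returns the trimmed panel plus a report.
#'
#' @param panel An `allele_panel`.
#' @param min_motif,max_motif,min_copies Passed to [find_tandem_repeats()].
#' @param threshold Passed to [extract_core()].
#' @return List with `panel` (an `allele_panel` of core sequences, same
#'   metadata) and `report` (data frame: `id`, `start`, `end`,
#'   `core_length`, `full_length`, `repeat_fraction_removed`, `fallback`).
#' @export
trim_cores <- function(panel, min_motif = 2L, max_motif = 12L,
                       min_copies = 3L, threshold = 0.1) {
  stopifnot(inherits(panel, "allele_panel"))
  ids <- names(panel$sequences)
  cores <- character(length(ids))
  rep_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- panel$sequences[[i]]
    ann <- find_tandem_repeats(s, min_motif, max_motif, min_copies)
    core <- extract_core(s, ann, threshold)
    cores[i] <- core$core_sequence
    rep_rows[[i]] <- data.frame(
      id = ids[i], start = core$start, end = core$end,
      core_length = core$end - core$start, full_length = nchar(s),
      repeat_fraction_removed = core$fraction_removed,
      fallback = core$full_sequence_fallback, stringsAsFactors = FALSE
    )
  }
  names(cores) <- ids
  list(panel = allele_panel(cores, panel$meta[, setdiff(names(panel$meta), "coding_length_bp")]),
       report = do.call(rbind, rep_rows))
}
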