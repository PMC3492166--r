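# Independent brute-force oracles. These deliberately re-derive results by
# direct enumeration rather than calling the implementation paths they check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# coverage mask of all positions inside any run of >= min_copies exact
# tandem copies of any motif with length in [mmin, mmax]
brute_repeat_cover <- function(seq, mmin, mmax, min_copies) {
  L <- nchar(seq)
  cov <- logical(L)
  for (m in mmin:mmax) {
    if (L < m * min_copies) next
    for (i in seq_len(L - m * min_copies + 1L)) {
      motif <- substr(seq, i, i + m - 1L)
      c_n <- 1L
      while (i + (c_n + 1L) * m - 1L <= L &&
             substr(seq, i + c_n * m, i + (c_n + 1L) * m - 1L) == motif) {
        c_n <- c_n + 1L
      }
      if (c_n >= min_copies) cov[i:(i + c_n * m - 1L)] <- TRUE
    }
  }
  cov
}

# longest window (0-based half-open) with repeat coverage <= threshold,
# scanning every (start, end) pair; leftmost tie-break
brute_core_window <- function(covered, threshold) {
  L <- length(covered)
  cum <- c(0L, cumsum(covered))
  best <- c(0L, 0L)
  for (a in 0:(L - 1L)) {
    for (b in (a + 1L):L) {
      if ((cum[b + 1L] - cum[a + 1L]) / (b - a) <= threshold &&
          (b - a) > (best[2] - best[1])) {
        best <- c(a, b)
      }
    }
  }
  best
}

# position-by-position binding-site scan (0-based starts)
brute_binding_sites <- function(primer, template, three_prime_exact,
                                max_total_mismatch, strand) {
  probe <- if (strand == "+") primer else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  p <- strsplit(probe, "")[[1]]
  t <- strsplit(template, "")[[1]]
  k <- length(p)
  hits <- integer(0); mms <- integer(0)
  for (i in seq_len(length(t) - k + 1L)) {
    w <- t[i:(i + k - 1L)]
    mm <- sum(w != p)
    idx3 <- if (strand == "+") seq(k - three_prime_exact + 1L, k) else
      seq_len(three_prime_exact)
    if (mm <= max_total_mismatch && sum(w[idx3] != p[idx3]) == 0L) {
      hits <- c(hits, i - 1L); mms <- c(mms, mm)
    }
  }
  data.frame(start = hits, mismatches = mms)
}

# longest k with suffix_k(p) complementary-antiparallel to suffix_k(q),
# via Biostrings (independent of the package's chartr-based revcomp)
brute_tail_complement <- function(p, q) {
  run <- 0L
  for (k in seq_len(min(nchar(p), nchar(q)))) {
    sp <- substr(p, nchar(p) - k + 1L, nchar(p))
    sq <- substr(q, nchar(q) - k + 1L, nchar(q))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    if (sp == rc) run <- k
  }
  run
}

# identity of two equal-length ungapped sequences
hamming_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y)
}

# exhaustive single-target primer-pair enumeration on an ungapped template
brute_candidates <- function(template, len_range, amplicon_min, amplicon_max,
                             gc_lo = 0, gc_hi = 1) {
  L <- nchar(template)
  gc_of <- function(s) {
    ch <- strsplit(s, "")[[1]]; mean(ch %in% c("G", "C"))
  }
  wins <- list()
  for (len in len_range) {
    for (s in 0:(L - len)) {
      sq <- substr(template, s + 1L, s + len)
      if (gc_of(sq) >= gc_lo && gc_of(sq) <= gc_hi) {
        wins[[length(wins) + 1L]] <- list(start = s, len = len, seq = sq)
      }
    }
  }
  out <- list()
  for (f in wins) for (r in wins) {
    if (r$start < f$start + f$len) next
    prod <- r$start + r$len - f$start
    if (prod < amplicon_min || prod > amplicon_max) next
    out[[length(out) + 1L]] <- data.frame(
      forward = f$seq,
      reverse = as.character(Biostrings::reverseComplement(Biostrings::DNAString(r$seq))),
      fwd_start = f$start, fwd_len = f$len,
      rev_start = r$start, rev_len = r$len,
      amplicon_len = prod, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# do two labelings induce the same partition?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ga <- split(seq_along(a), a)
  gb <- split(seq_along(b), b)
  setequal(lapply(ga, sort), lapply(gb, sort))
}
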