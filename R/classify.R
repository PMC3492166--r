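# scoring used for global (Needleman-Wunsch) pairwise alignment:
# match +1, mismatch -1, N mismatches everything (including N),
# gap opening 2, gap extension 1
.pq_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}

.aligned_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y & x != "-" & x != "N" & y != "N")
}

#' Pairwise identity of two nucleotide sequences
#'
#' Globally aligns the two sequences (Needleman-Wunsch; match +1, mismatch
#' -1, gap opening 2, gap extension 1) and returns the fraction of aligned
#' columns that match. Gap columns count in the denominator and `N` is
#' always a mismatch, so identity is conservative. Hordein-type families
#' sit in the 0.80-0.99 band on this measure.
#'
#' @param a,b Nucleotide strings (uppercase ACGTN). If both already contain
#'   gap characters (`-`) and have equal length they are treated as aligned
#'   rows and scored column-wise without re-alignment.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE)) {
    return(.aligned_identity(a, b))
  }
  if (a == b) return(1)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = .pq_submat(),
    gapOpening = 2, gapExtension = 1
  )
  .aligned_identity(as.character(Biostrings::alignedPattern(pa)),
                    as.character(Biostrings::alignedSubject(pa)))
}

#' Multiple alignment of a sequence group
#'
#' Aligns two sequences by global Needleman-Wunsch (same scoring as
#' [pairwise_identity()]); three or more via the MAFFT progressive aligner
#' (deterministic FFT-NS-2 settings). A single sequence is returned as an
#' identity alignment. Removing the gaps from any output row reproduces the
#' corresponding input sequence exactly; this is asserted before returning.
#'
#' @param sequences Named character vector of ungapped sequences.
#' @param source Label recording what was aligned (`"core"` or `"full"`).
#' @return Object of class `group_alignment`: list with `ids`, `rows`
#'   (named character vector of equal-length gapped rows, uppercase) and
#'   `source`.
#' @export
align_group <- function(sequences, source = "core") {
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named")
  stopifnot(length(sequences) >= 1)
  if (length(sequences) == 1L) {
    rows <- unname(sequences)
  } else if (length(sequences) == 2L) {
    pa <- Biostrings::pairwiseAlignment(
      sequences[[1]], sequences[[2]], type = "global",
      substitutionMatrix = .pq_submat(), gapOpening = 2, gapExtension = 1
    )
    rows <- c(as.character(Biostrings::alignedPattern(pa)),
              as.character(Biostrings::alignedSubject(pa)))
  } else {
    fin <- tempfile(fileext = ".fa")
    fout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(fin, fout)))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), fin)
    status <- system2("mafft",
                      c("--retree", "2", "--maxiterate", "0", "--inputorder",
                        "--quiet", fin),
                      stdout = fout, stderr = FALSE)
    if (status != 0) stop("mafft failed with exit status ", status)
    aln <- Biostrings::readDNAStringSet(fout)
    rows <- toupper(as.character(aln))
    rows <- unname(rows[match(ids, sub("\\s.*$", "", names(aln)))])
  }
  names(rows) <- ids
  stopifnot(length(unique(nchar(rows))) == 1L)
  degapped <- gsub("-", "", rows, fixed = TRUE)
  if (!identical(unname(degapped), unname(toupper(sequences)))) {
    stop("alignment failed round-trip check: rows do not reproduce inputs")
  }
  structure(list(ids = ids, rows = rows, source = source),
            class = "group_alignment")
}

#' @export
print.group_alignment <- function(x, ...) {
  cat("group_alignment:", length(x$rows), "rows x", nchar(x$rows[[1]]),
      "columns (", x$source, ")\n")
  invisible(x)
}

#' Pairwise p-distance matrix of an alignment
#'
#' Distance between rows `i` and `j` is `1 - identity` scored column-wise
#' on the gapped rows (gaps and `N` count as mismatches).
#'
#' @param alignment A `group_alignment`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
alignment_distances <- function(alignment) {
  stopifnot(inherits(alignment, "group_alignment"))
  rows <- alignment$rows
  n <- length(rows)
  chars <- lapply(rows, function(r) strsplit(r, "")[[1]])
  D <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      x <- chars[[i]]; y <- chars[[j]]
      d <- 1 - mean(x == y & x != "-" & x != "N" & y != "N")
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree of a sequence group
#'
#' Builds a neighbor-joining tree on the p-distance matrix of the alignment
#' and midpoint-roots it. A light distance method is used deliberately: for
#' families at >80% identity the subfamily arrangement is robust to the
#' inference engine (full-length, core and protein inputs give the same
#' groupings), so NJ on p-distance suffices for classification.
#'
#' @param alignment A `group_alignment` with at least 2 rows.
#' @return A rooted `phylo` object (ape); for exactly 2 rows, a trivial
#'   two-leaf tree. Use [ape::write.tree()] for Newick output.
#' @export
build_tree <- function(alignment) {
  stopifnot(inherits(alignment, "group_alignment"))
  n <- length(alignment$rows)
  if (n < 2) stop("need at least 2 sequences to build a tree")
  D <- alignment_distances(alignment)
  if (n == 2) {
    d <- D[1, 2]
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         alignment$ids[1], d / 2,
                                         alignment$ids[2], d / 2)))
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0  # NJ can emit tiny negatives
  phangorn::midpoint(tr)
}

# depth of every node (root distance); root = n_tip + 1 in ape convention
.node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# partition leaves by cutting the rooted tree at height h from the root:
# each group is the clade below the first node at depth >= h on the path
# from the root; h <= 0 puts everything in one group
.cut_at_height <- function(tree, h) {
  if (h <= 0) return(list(tree$tip.label))
  depths <- .node_depths(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  groups <- list()
  walk <- function(node) {
    if (node <= ntip) {
      groups[[length(groups) + 1L]] <<- tree$tip.label[node]
    } else if (depths[node] >= h) {
      tips <- phangorn::Descendants(tree, node, "tips")[[1]]
      groups[[length(groups) + 1L]] <<- tree$tip.label[tips]
    } else {
      for (child in tree$edge[tree$edge[, 1] == node, 2]) walk(child)
    }
    invisible()
  }
  walk(root)
  groups
}

#' Cut a rooted tree into subfamily groups
#'
#' Partitions the panel members into groups that are contiguous clades of
#' the (midpoint-rooted) tree, either at a fixed root-distance threshold or
#' by searching the threshold that yields exactly `k` groups. Curated
#' family annotations typically fix group counts per family by inspection
#' (e.g. B1/B2/B3), so `k_groups` is the primary mode; `threshold`
#' supports automation.
#'
#' @param tree A rooted `phylo` (from [build_tree()]); an unrooted tree is
#'   midpoint-rooted first.
#' @param panel Optional `allele_panel` whose members must equal the tree
#'   leaves.
#' @param mode `"k_groups"` or `"threshold"`.
#' @param value Number of groups, or (threshold mode) a divergence scale
#'   measured down from the deepest leaf: subtrees whose divergence from the
#'   rest exceeds the threshold separate, and a threshold larger than the
#'   tree depth leaves a single group.
#' @return Object of class `family_classification`: list with `tree`,
#'   `groups` (named list subfamily -> member ids, named `"G1"`, `"G2"`, ...
#'   in tree traversal order) and `assignment` (data frame `id`,
#'   `subfamily`).
#' @export
cut_subfamilies <- function(tree, panel = NULL,
                            mode = c("k_groups", "threshold"), value) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "allele_panel"))
    if (!setequal(tree$tip.label, names(panel$sequences))) {
      stop("tree leaves do not match panel member ids")
    }
  }
  ntip <- length(tree$tip.label)
  if (mode == "threshold") {
    groups <- .cut_at_height(tree, max(.node_depths(tree)) - value)
  } else {
    k <- as.integer(value)
    if (k == 1L) {
      groups <- list(tree$tip.label)
    } else if (k == ntip) {
      groups <- as.list(tree$tip.label)
    } else {
      depths <- .node_depths(tree)
      cand <- sort(unique(depths[depths > 0]))
      sizes <- integer(0)
      groups <- NULL
      for (h in cand) {
        g <- .cut_at_height(tree, h)
        sizes <- c(sizes, length(g))
        if (length(g) == k) { groups <- g; break }
      }
      if (is.null(groups)) {
        stop("no cut height yields ", k, " groups; achievable group counts: ",
             paste(sort(unique(c(1L, sizes, ntip))), collapse = ", "))
      }
    }
  }
  names(groups) <- paste0("G", seq_along(groups))
  assignment <- data.frame(
    id = unlist(groups, use.names = FALSE),
    subfamily = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE
  )
  assignment <- assignment[match(tree$tip.label, assignment$id), , drop = FALSE]
  rownames(assignment) <- NULL
  structure(list(tree = tree, groups = groups, assignment = assignment),
            class = "family_classification")
}

#' @export
print.family_classification <- function(x, ...) {
  cat("family_classification:", length(x$groups), "group(s)\n")
  for (g in names(x$groups)) {
    cat(" ", g, ":", paste(x$groups[[g]], collapse = ", "), "\n")
  }
  invisible(x)
}
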