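#' Construct an allele panel
#'
#' An allele panel holds the coding sequences of a multigene family (or a set
#' of families) together with provenance metadata. It is the common input of
#' the repeat-trimming, classification, primer-design and in-silico PCR
#' steps.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   coding sequences. Names are the record ids and must be unique. Sequences
#'   are uppercased on ingest; only `A`, `C`, `G`, `T`, `N` are accepted
#'   (`N` is treated as a mismatch by all downstream comparisons).
#' @param meta Data frame with one row per record: columns `id` and `family`
#'   are required; `accession`, `cultivar` and `subfamily` are optional and
#'   default to the empty string.
#' @return An object of class `allele_panel`: a list with elements
#'   `sequences` (named uppercase character vector), `meta` (data frame with
#'   `coding_length_bp` recomputed from the sequences) and `family_index`
#'   (list mapping family label to record ids).
#' @export
allele_panel <- function(sequences, meta) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  sequences <- toupper(sequences)
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(sequences) == 0L)) {
    stop("empty sequence for: ", paste(ids[nchar(sequences) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("id", "family") %in% names(meta))) {
    stop("metadata must have columns 'id' and 'family'")
  }
  for (col in c("accession", "cultivar")) {
    if (is.null(meta[[col]])) meta[[col]] <- ""
  }
  missing_meta <- setdiff(ids, meta$id)
  orphan_meta <- setdiff(meta$id, ids)
  if (length(missing_meta) || length(orphan_meta)) {
    stop(
      "id mismatch between sequences and metadata",
      if (length(missing_meta)) paste0("; sequences without metadata: ",
                                       paste(missing_meta, collapse = ", ")),
      if (length(orphan_meta)) paste0("; metadata without sequence: ",
                                      paste(orphan_meta, collapse = ", "))
    )
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  meta$coding_length_bp <- unname(nchar(sequences))
  structure(
    list(
      sequences = sequences,
      meta = meta,
      family_index = split(meta$id, meta$family)
    ),
    class = "allele_panel"
  )
}

#' @export
print.allele_panel <- function(x, ...) {
  fam <- vapply(x$family_index, length, integer(1))
  cat("allele_panel:", length(x$sequences), "records in",
      length(fam), "family(ies)\n")
  cat(paste0("  ", names(fam), ": ", fam, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
length.allele_panel <- function(x) length(x$sequences)

#' Subset an allele panel by record id
#'
#' @param panel An `allele_panel`.
#' @param ids Record ids to keep (order preserved).
#' @return A new `allele_panel` restricted to `ids`.
#' @export
subset_panel <- function(panel, ids) {
  stopifnot(inherits(panel, "allele_panel"))
  missing <- setdiff(ids, names(panel$sequences))
  if (length(missing)) stop("unknown record id(s): ", paste(missing, collapse = ", "))
  allele_panel(panel$sequences[ids], panel$meta[match(ids, panel$meta$id), , drop = FALSE])
}

#' Read an allele panel from FASTA plus metadata TSV
#'
#' The metadata file is tab-separated with a header; columns `id` and
#' `family` are required, `accession`, `cultivar` and `subfamily` optional.
#' Coding lengths are always recomputed from the sequences.
#'
#' @param fasta_path Path to a FASTA file of coding sequences (wrapped or
#'   single-line).
#' @param metadata_path Path to the metadata TSV.
#' @return An `allele_panel`.
#' @export
load_panel <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character", comment.char = "#")
  allele_panel(seqs, meta)
}

#' Write an allele panel to FASTA plus metadata TSV
#'
#' Inverse of [load_panel()]: `load_panel()` on the written files reproduces
#' the panel exactly.
#'
#' @param panel An `allele_panel`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, fasta_path, metadata_path) {
  stopifnot(inherits(panel, "allele_panel"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$sequences), fasta_path)
  utils::write.table(panel$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(panel)
}
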