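#' Bundled barley hordein study tables
#'
#' Plain-text tables for the barley (*Hordeum vulgare*) hordein
#' storage-protein gene families and the qRT-PCR assays built on them,
#' shipped as package example data:
#'
#' * `"genes"` -- family members and reference genes (actin, ubiquitin,
#'   PTF/GOS2) with database accession, source cultivar and coding-region
#'   length (bp), the length used for mass-to-mole conversion.
#' * `"primers"` -- validated primer sets for whole families (B, C, D),
#'   the gamma1/gamma3 subfamilies, subgroups and individual members,
#'   plus the three reference genes.
#' * `"clone_mixture"` -- pooled cloned-DNA validation: amounts added to
#'   the pool vs amounts recalculated from Ct through the actin standard
#'   curve (amol/ul, mean and SD).
#' * `"reference_stability"` -- pairwise reference-gene mole ratios
#'   (mean and SD) across grain development (days after pollination).
#' * `"grain_proportions"` -- percentage contribution of each assay's
#'   signal to the total hordein transcript pool at 10/15/18/25 DAP
#'   (actin-normalized); `NA` marks assays with no product in the studied
#'   cultivar.
#'
#' @param name One of `"genes"`, `"primers"`, `"clone_mixture"`,
#'   `"reference_stability"`, `"grain_proportions"`.
#' @return A data frame.
#' @export
hordein_data <- function(name = c("genes", "primers", "clone_mixture",
                                  "reference_stability",
                                  "grain_proportions")) {
  name <- match.arg(name)
  file <- c(
    genes = "hordein_genes.tsv",
    primers = "hordein_primers.tsv",
    clone_mixture = "clone_mixture.tsv",
    reference_stability = "reference_stability.tsv",
    grain_proportions = "grain_proportions.tsv"
  )[[name]]
  path <- system.file("extdata", file, package = "primequant", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
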