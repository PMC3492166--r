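Package: primequant
Title: Allele-Discriminating Primer Design and Absolute qPCR Quantification
    for Homologous Multigene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative RT-PCR assays on multigene families
    whose members share very high sequence identity, such as the barley
    hordein storage-protein genes. Detects tandem-repeat regions and trims
    coding sequences to low-repeat cores, classifies family members into
    subfamilies by neighbor-joining on pairwise distance, enumerates and
    ranks primer pairs that discriminate targets through 3'-terminal
    mismatches, predicts amplification in silico against the whole paralog
    panel, and converts threshold-cycle values to absolute transcript
    amounts (attomoles) through a standard curve with reference-gene
    normalization, stability diagnostics, and family contribution reports.
    Includes a synthetic homologous-family generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    graphics,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
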