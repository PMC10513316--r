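Package: blockerpcr
Title: Design and Analysis of Blocker-Mediated Allele-Specific PCR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and analysing blocker-mediated
    allele-specific PCR assays that detect a single-nucleotide variant
    at low allele fraction, such as the canine BRAF V595E mutation in
    urine-sediment DNA. Covers nearest-neighbor duplex thermodynamics
    with salt correction for primer and blocker melting temperatures,
    enumeration and scoring of allele-specific primer/blocker/opposite
    primer combinations around the variant, qPCR positive/negative call
    logic with melt-curve specificity filtering, serial-dilution
    sensitivity modelling, demultiplexing and counting of barcoded
    amplicon reads to estimate the mutant allele ratio, cross-method
    concordance summaries, and simulators that generate amplicon reads
    and qPCR records so the whole pipeline can be exercised without
    wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
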