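Package: snpmelt
Title: SNP Genotyping by Differentially Melting Amplicons: Assay Design,
    Melt-Curve and Cq Calling, and Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A low-cost SNP genotyping toolkit built around three-primer
    allele-specific PCR with deliberately mismatched primers, so that the two
    allele products melt at different temperatures (competitive amplification
    of differentially melting amplicons, CADMA). Designs wild-type-specific,
    mutant-specific and common primers for a biallelic locus, predicts primer
    and amplicon melting temperatures with a nearest-neighbor model, and routes
    each assay to high-resolution melting (HRM) or allele-specific qPCR
    (AS-qPCR) by primer Tm. Calls genotypes from raw plate fluorescence:
    normalized melt curves classified against known-genotype reference
    controls for HRM, and dual-reaction quantification-cycle (Cq) thresholding
    for AS-qPCR, with duplicate-well concordance. Computes case-control
    genotype and allele frequencies, Pearson chi-square tests, and odds ratios
    with Woolf 95% confidence intervals, including dominant-model collapsing.
    A seeded simulator generates cohorts and instrument-like fluorescence
    traces so the full pipeline is testable without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    withr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
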