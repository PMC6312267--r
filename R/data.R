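# Accessors for the bundled example data: a published PCOS case-control
# genotype count table and the allele-specific primer pairs of the assays it
# was genotyped with.

#' Bundled PCOS case-control genotype counts
#'
#' Genotype counts for seven reproductive-axis SNPs (FTO rs9939609, GnRH1
#' rs6185, FSHB rs6169, FSHR rs6165, LHB rs1800447/rs34349826, LHCGR
#' rs2293275, INSR rs1799817) in a cohort of 55 PCOS cases and 110 controls,
#' genotyped with the three-primer HRM/AS-qPCR assays this package designs.
#' The two LHB loci are monomorphic in this population.
#'
#' @return A `genotype_table` tibble with columns `rsid`, `gene`,
#'   `genotype`, `cases`, `controls`, `reference`.
#' @examples
#' counts <- pcos_genotype_counts()
#' associate_all(counts)
#' @export
pcos_genotype_counts <- function() {
  read_counts_tsv(system.file("extdata", "pcos_genotype_counts.tsv",
                              package = "snpmelt"))
}

#' Bundled published primer pairs
#'
#' The wild-type-specific, mutant-specific and common primers of the seven
#' assays behind [pcos_genotype_counts()], with the allele carried by each
#' allele-specific primer on its own strand. Useful as rule-compliance
#' fixtures for [check_primer_pair()].
#'
#' @return Tibble with columns `rsid`, `gene`, `method`, `orientation`,
#'   `wild_allele`, `mut_allele`, `wild_primer`, `mutant_primer`,
#'   `common_primer`.
#' @export
published_primers <- function() {
  readr::read_tsv(system.file("extdata", "published_primers.tsv", package = "snpmelt"),
                  comment = "#", show_col_types = FALSE)
}
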