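# End-to-end pipeline drivers, wrapped by the command-line script in
# inst/cli/snpmelt.R. Each writes its artifacts to disk with a version +
# config-hash header and returns the main result invisibly; any module error
# propagates (the CLI converts it to a non-zero exit status).

#' Design triplets for a file of SNP targets
#'
#' @param targets_path Bracket-notation TSV (or `.fa`/`.fasta` file) of SNP
#'   targets.
#' @param out_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param constraints A [design_config()].
#' @return Invisibly, the list of designed triplets.
#' @export
pipeline_design <- function(targets_path, out_prefix, constraints = design_config()) {
  targets <- if (grepl("\\.fa(sta)?$", targets_path, ignore.case = TRUE)) {
    read_snp_targets_fasta(targets_path)
  } else {
    read_snp_targets_tsv(targets_path)
  }
  triplets <- purrr::map(targets, design_triplet, constraints = constraints)
  tab <- triplets_to_tibble(triplets)
  write_with_header(tab, paste0(out_prefix, ".tsv"), constraints)
  jsonlite::write_json(
    purrr::map(triplets, function(tr) tr[setdiff(names(tr), "config")]),
    paste0(out_prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(triplets)
}

#' Simulate a genotyping experiment to plate files
#'
#' @param out_dir Output directory (created if needed); writes
#'   `melt_plate.csv`, `qpcr_plate.csv`, `manifest.csv`,
#'   `qpcr_manifest.csv` and `truth.tsv`.
#' @param spec A [cohort_spec()].
#' @param triplet A `primer_triplet` (or list with `amplicon_tms`).
#' @param noise A [curve_noise_model()].
#' @param seed Integer seed.
#' @return Invisibly, the [simulate_experiment()] list.
#' @export
pipeline_simulate <- function(out_dir, spec = cohort_spec(),
                              triplet, noise = curve_noise_model(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(spec, triplet, noise, seed = seed)
  cfg <- list(spec = unclass(spec), noise = unclass(noise), seed = seed)
  write_with_header(sim$melt_plate, file.path(out_dir, "melt_plate.csv"), cfg, delim = ",")
  write_with_header(sim$qpcr_plate, file.path(out_dir, "qpcr_plate.csv"), cfg, delim = ",")
  write_with_header(sim$manifest, file.path(out_dir, "manifest.csv"), cfg, delim = ",")
  write_with_header(sim$qpcr_manifest, file.path(out_dir, "qpcr_manifest.csv"), cfg, delim = ",")
  write_with_header(sim$cohort, file.path(out_dir, "truth.tsv"), cfg)
  invisible(sim)
}

#' Call genotypes from an HRM plate file
#'
#' @param plate_path Melt plate CSV.
#' @param manifest_path Manifest CSV.
#' @param rsid Locus identifier for the calls.
#' @param out_tsv Output calls TSV.
#' @param pre_window,post_window Normalization windows.
#' @param ambiguity_ratio Minimum per-replicate confidence.
#' @param vcf_path Optional VCF output; needs `ref_allele`/`alt_allele`.
#' @param ref_allele,alt_allele Alleles for the VCF.
#' @return Invisibly, the calls tibble.
#' @export
pipeline_call_hrm <- function(plate_path, manifest_path, rsid, out_tsv,
                              pre_window = c(72, 76), post_window = c(90, 94),
                              ambiguity_ratio = 0.2,
                              vcf_path = NULL, ref_allele = NULL, alt_allele = NULL) {
  plate <- read_plate_csv(plate_path, "melt")
  manifest <- read_manifest_csv(manifest_path)
  cfg <- list(pre_window = pre_window, post_window = post_window,
              ambiguity_ratio = ambiguity_ratio, rsid = rsid)
  calls <- call_hrm_plate(plate, manifest, rsid, pre_window, post_window,
                          ambiguity_ratio)
  write_calls_tsv(calls, out_tsv, cfg)
  if (!is.null(vcf_path)) {
    write_vcf(calls, ref_allele %||% "N", alt_allele %||% "N", vcf_path)
  }
  invisible(calls)
}

#' Call genotypes from an AS-qPCR plate file
#'
#' @param plate_path Amplification plate CSV.
#' @param manifest_path Manifest CSV (wells matching the qPCR plate).
#' @param rsid Locus identifier for the calls.
#' @param out_tsv Output calls TSV.
#' @param cutoff Cq positivity cutoff (default 30).
#' @param threshold Fluorescence threshold for [compute_cq()].
#' @param vcf_path,ref_allele,alt_allele Optional VCF output.
#' @return Invisibly, the calls tibble.
#' @export
pipeline_call_qpcr <- function(plate_path, manifest_path, rsid, out_tsv,
                               cutoff = 30, threshold = 50,
                               vcf_path = NULL, ref_allele = NULL, alt_allele = NULL) {
  plate <- read_plate_csv(plate_path, "qpcr")
  manifest <- read_manifest_csv(manifest_path)
  cfg <- list(cutoff = cutoff, threshold = threshold, rsid = rsid)
  calls <- call_qpcr_plate(plate, manifest, rsid, cutoff, threshold)
  write_calls_tsv(calls, out_tsv, cfg)
  if (!is.null(vcf_path)) {
    write_vcf(calls, ref_allele %||% "N", alt_allele %||% "N", vcf_path)
  }
  invisible(calls)
}

#' Case-control association from counts, or from calls plus phenotypes
#'
#' Either read a ready counts TSV, or cross-tabulate a calls TSV against a
#' phenotype CSV (`sample_id`, `status` = `case`/`control`) using the locus
#' alleles to label genotypes in allele-pair style (reference allele first).
#'
#' @param out_tsv Output report TSV.
#' @param counts_path Counts TSV (takes precedence when given).
#' @param calls_path,phenotype_path Calls TSV and phenotype CSV.
#' @param ref_allele,alt_allele Allele letters used to build genotype labels
#'   from calls.
#' @param level Confidence level.
#' @return Invisibly, the association comparisons tibble.
#' @export
pipeline_assoc <- function(out_tsv, counts_path = NULL,
                           calls_path = NULL, phenotype_path = NULL,
                           ref_allele = "A", alt_allele = "B", level = 0.95) {
  counts <- if (!is.null(counts_path)) {
    read_counts_tsv(counts_path)
  } else {
    if (is.null(calls_path) || is.null(phenotype_path)) {
      snpmelt_abort("need either counts_path or calls_path + phenotype_path", "invalid_input")
    }
    calls <- read_checked(calls_path,
                          function(p) readr::read_tsv(p, comment = "#", show_col_types = FALSE),
                          "calls", c("sample_id", "rsid", "call"))
    pheno <- read_checked(phenotype_path,
                          function(p) readr::read_csv(p, comment = "#", show_col_types = FALSE),
                          "phenotype", c("sample_id", "status"))
    calls_to_counts(calls, pheno, ref_allele, alt_allele)
  }
  results <- associate_all(counts, level)
  write_assoc_tsv(results, out_tsv, list(level = level))
  invisible(results)
}

#' Cross-tabulate genotype calls against case/control status
#'
#' Genotype labels follow allele-pair style built from the locus alleles,
#' reference allele first (`TT`, `TA`, `AA` for ref `T`, alt `A`). No-calls
#' are dropped with a message.
#'
#' @param calls Calls tibble (`sample_id`, `rsid`, `call`).
#' @param phenotypes Tibble (`sample_id`, `status` in `case`/`control`).
#' @param ref_allele,alt_allele Locus alleles.
#' @return A `genotype_table` tibble.
#' @export
calls_to_counts <- function(calls, phenotypes, ref_allele, alt_allele) {
  labels <- c(hom_ref = strrep(ref_allele, 2),
              het = paste0(ref_allele, alt_allele),
              hom_alt = strrep(alt_allele, 2))
  merged <- dplyr::inner_join(calls, phenotypes, by = "sample_id")
  n_nc <- sum(merged$call == "no_call")
  if (n_nc > 0) {
    message(sprintf("dropping %d no-call sample(s) from the association table", n_nc))
    merged <- merged[merged$call != "no_call", ]
  }
  bad_status <- setdiff(unique(merged$status), c("case", "control"))
  if (length(bad_status)) {
    snpmelt_abort(sprintf("phenotype status must be case/control, found: %s",
                          paste(bad_status, collapse = ", ")), "invalid_input")
  }
  counts <- merged |>
    dplyr::count(.data$rsid, .data$call, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
  for (col in c("case", "control")) if (!col %in% names(counts)) counts[[col]] <- 0L
  full <- tidyr::expand_grid(rsid = unique(calls$rsid), call = names(labels)) |>
    dplyr::left_join(counts, by = c("rsid", "call")) |>
    dplyr::mutate(genotype = unname(labels[.data$call]),
                  cases = dplyr::coalesce(.data$case, 0L),
                  controls = dplyr::coalesce(.data$control, 0L),
                  reference = .data$call == "hom_ref") |>
    dplyr::select("rsid", "genotype", "cases", "controls", "reference")
  class(full) <- c("genotype_table", class(tibble::tibble()))
  full
}
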