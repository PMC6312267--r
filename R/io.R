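# File formats: counts TSV, plate CSVs, well manifests, SNP target TSV/FASTA,
# genotype-call TSV and a minimal VCF. All writers stamp a comment header with
# the tool version and a hash of the run configuration so outputs are
# traceable and byte-reproducible (no timestamps).

snpmelt_version <- function() {
  as.character(utils::packageVersion("snpmelt"))
}

output_header <- function(config = list()) {
  c(sprintf("# snpmelt %s", snpmelt_version()),
    sprintf("# config_hash=%s", rlang::hash(config)))
}

write_with_header <- function(df, path, config = list(), delim = "\t") {
  writeLines(output_header(config), path)
  readr::write_delim(df, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_checked <- function(path, reader, what, required) {
  if (!file.exists(path)) {
    snpmelt_abort(sprintf("%s file not found: %s", what, path), "io")
  }
  df <- tryCatch(reader(path),
                 error = function(e) snpmelt_abort(
                   sprintf("failed to parse %s file %s: %s", what, path, conditionMessage(e)),
                   "io"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    snpmelt_abort(sprintf("%s file %s lacks required columns: %s",
                          what, path, paste(missing, collapse = ", ")), "io")
  }
  df
}

#' Read a genotype counts table
#'
#' Tab-separated with columns `rsid`, `genotype`, `cases`, `controls`,
#' `reference` (logical), optionally `gene`. Comment lines starting `#` are
#' skipped.
#'
#' @param path File path.
#' @return A `genotype_table`-classed tibble (possibly multi-locus).
#' @export
read_counts_tsv <- function(path) {
  df <- read_checked(path,
                     function(p) readr::read_tsv(p, comment = "#", show_col_types = FALSE),
                     "counts", c("rsid", "genotype", "cases", "controls", "reference"))
  df$reference <- as.logical(df$reference)
  df$cases <- as.integer(df$cases)
  df$controls <- as.integer(df$controls)
  class(df) <- c("genotype_table", class(tibble::tibble()))
  df
}

#' Read a long-format fluorescence plate CSV
#'
#' Melt plates need columns `well`, `sample_id`, `replicate`, `temperature`,
#' `fluorescence`; amplification plates need `well`, `sample_id`,
#' `replicate`, `allele_primer`, `cycle`, `fluorescence`.
#'
#' @param path File path.
#' @param type `"melt"` or `"qpcr"`.
#' @return Tibble in the layout the plate callers expect.
#' @export
read_plate_csv <- function(path, type = c("melt", "qpcr")) {
  type <- match.arg(type)
  required <- if (type == "melt") {
    c("well", "sample_id", "replicate", "temperature", "fluorescence")
  } else {
    c("well", "sample_id", "replicate", "allele_primer", "cycle", "fluorescence")
  }
  read_checked(path,
               function(p) readr::read_csv(p, comment = "#", show_col_types = FALSE),
               paste(type, "plate"), required)
}

#' Read a plate manifest CSV
#'
#' Maps wells to samples and marks known-genotype control wells: columns
#' `well`, `sample_id`, `role` (`sample`/`control`), `genotype` (controls).
#'
#' @param path File path.
#' @return Manifest tibble.
#' @export
read_manifest_csv <- function(path) {
  df <- read_checked(path,
                     function(p) readr::read_csv(p, comment = "#", show_col_types = FALSE),
                     "manifest", c("well", "sample_id", "role"))
  bad <- setdiff(unique(df$role), c("sample", "control"))
  if (length(bad)) {
    snpmelt_abort(sprintf("manifest roles must be sample/control, found: %s",
                          paste(bad, collapse = ", ")), "io")
  }
  df
}

#' Read SNP targets from a bracket-notation TSV
#'
#' Tab-separated with columns `rsid` and `sequence`, where the sequence marks
#' the SNP as `[ref/alt]`, e.g. `ACGT...[C/T]...ACGT`.
#'
#' @param path File path.
#' @return List of [snp_target()] objects, named by rsid.
#' @export
read_snp_targets_tsv <- function(path) {
  df <- read_checked(path,
                     function(p) readr::read_tsv(p, comment = "#", show_col_types = FALSE),
                     "targets", c("rsid", "sequence"))
  targets <- purrr::map2(df$rsid, df$sequence, function(rsid, s) {
    m <- regmatches(s, regexec("^([ACGTNacgtn]*)\\[([ACGT])/([ACGT])\\]([ACGTNacgtn]*)$", s))[[1]]
    if (length(m) != 5L) {
      snpmelt_abort(sprintf("target %s: sequence is not in NNN[X/Y]NNN bracket notation", rsid),
                    "io")
    }
    snp_target(rsid, m[2], m[5], m[3], m[4])
  })
  stats::setNames(targets, df$rsid)
}

#' Read SNP targets from a FASTA file
#'
#' Each record's sequence is the target with the reference allele at the SNP;
#' the header carries the locus metadata as `>rsid pos=<1-based> ref=<base>
#' alt=<base>`. Requires the Biostrings package.
#'
#' @param path FASTA file path.
#' @return List of [snp_target()] objects, named by rsid.
#' @export
read_snp_targets_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    snpmelt_abort("reading FASTA targets requires the Biostrings package", "io")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  purrr::imap(as.list(as.character(seqs)), function(s, header) {
    get_field <- function(key) {
      m <- regmatches(header, regexec(paste0(key, "=([A-Za-z0-9]+)"), header))[[1]]
      if (length(m) != 2L) {
        snpmelt_abort(sprintf("FASTA header '%s' lacks %s=", header, key), "io")
      }
      m[2]
    }
    rsid <- strsplit(header, "\\s+")[[1]][1]
    pos <- as.integer(get_field("pos"))
    ref <- toupper(get_field("ref")); alt <- toupper(get_field("alt"))
    if (substr(s, pos, pos) != ref) {
      snpmelt_abort(sprintf("target %s: base at pos %d is %s, not the declared ref %s",
                            rsid, pos, substr(s, pos, pos), ref), "io")
    }
    snp_target(rsid, substr(s, 1L, pos - 1L), substr(s, pos + 1L, nchar(s)), ref, alt)
  }) |>
    stats::setNames(vapply(names(seqs), function(h) strsplit(h, "\\s+")[[1]][1], character(1)))
}

#' Flatten primer triplets to a tibble
#'
#' One row per primer in grouped-triplet order (wild, mutant, common per
#' locus), sequences written 5'->3'.
#'
#' @param triplets A `primer_triplet` or list of them.
#' @return Tibble: `rsid`, `role`, `allele`, `sequence`, `primer_tm`,
#'   `amplicon_tm`, `method`, `annealing_temp`, `orientation`, `separation`.
#' @export
triplets_to_tibble <- function(triplets) {
  if (inherits(triplets, "primer_triplet")) triplets <- list(triplets)
  purrr::map_dfr(triplets, function(tr) {
    tibble::tibble(
      rsid = tr$rsid,
      role = c("wild", "mutant", "common"),
      allele = c(tr$ref_allele, tr$alt_allele, NA_character_),
      sequence = c(tr$wild_primer, tr$mutant_primer, tr$common_primer),
      primer_tm = unname(tr$primer_tms[c("wild", "mutant", "common")]),
      amplicon_tm = c(unname(tr$amplicon_tms[c("wild", "mutant")]), NA_real_),
      method = tr$method,
      annealing_temp = tr$annealing_temp,
      orientation = tr$orientation,
      separation = tr$separation
    )
  })
}

#' Write genotype calls as TSV
#'
#' @param calls Calls tibble from [call_hrm_plate()] or [call_qpcr_plate()].
#' @param path Output path.
#' @param config Run configuration recorded in the header hash.
#' @export
write_calls_tsv <- function(calls, path, config = list()) {
  write_with_header(calls, path, config)
}

#' Write genotype calls as a minimal VCF
#'
#' One record per locus, `ID` = rsid, genotypes as `GT` fields (`0/0`, `0/1`,
#' `1/1`, `./.` for no-calls). Positions are unknown to the caller, so
#' `CHROM`/`POS` are placeholders unless supplied.
#'
#' @param calls Calls tibble (single locus).
#' @param ref_allele,alt_allele Locus alleles for the REF/ALT columns.
#' @param path Output path.
#' @param chrom,pos Optional coordinates.
#' @export
write_vcf <- function(calls, ref_allele, alt_allele, path, chrom = ".", pos = 1L) {
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", no_call = "./.")
  unknown <- setdiff(unique(calls$call), names(gt))
  if (length(unknown)) {
    snpmelt_abort(sprintf("unknown call values: %s", paste(unknown, collapse = ", ")), "io")
  }
  rsid <- unique(calls$rsid)
  if (length(rsid) != 1L) {
    snpmelt_abort("write_vcf expects calls for a single locus", "io")
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=snpmelt-%s", snpmelt_version()),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            calls$sample_id), collapse = "\t"),
    paste(c(chrom, pos, rsid, ref_allele, alt_allele, ".", ".", ".", "GT",
            unname(gt[calls$call])), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write an association report as TSV
#'
#' @param results Comparison tibble ([associate_all()] output or
#'   `snp_assoc$results`).
#' @param path Output path.
#' @param config Run configuration recorded in the header hash.
#' @export
write_assoc_tsv <- function(results, path, config = list()) {
  if (inherits(results, "snp_assoc")) results <- results$results
  write_with_header(results, path, config)
}
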