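# Melting-temperature models.
#
# Primers use the unified nearest-neighbor (NN) thermodynamic model with a
# monovalent-salt entropy correction; amplicons use a GC-fraction + length
# formula with a log-salt term. Assay design deliberately introduces primer
# mutations; because those mutations are copied into the product from cycle 2
# onward, the *matched* NN Tm of the final primer sequence is what routing and
# annealing decisions use, while first-cycle primer-template duplexes with
# unincorporated mismatches take a fixed per-mismatch penalty.

.nn_cache <- new.env(parent = emptyenv())

#' Load nearest-neighbor thermodynamic parameters
#'
#' Reads the packaged unified NN table (stacking dH/dS for the ten unique
#' dinucleotide steps, duplex initiation terms, symmetry correction, salt and
#' gas constants) or a user-supplied JSON file with the same layout.
#'
#' @param path Path to a JSON parameter file; `NULL` (default) loads the
#'   packaged table.
#' @return A list with elements `stacks`, `initiation`, `symmetry`,
#'   `salt_dS_per_phosphate_pair` and `gas_constant`.
#' @export
load_nn_params <- function(path = NULL) {
  key <- path %||% "__packaged__"
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  file <- path %||% system.file("extdata", "nn_unified.json", package = "snpmelt")
  if (!nzchar(file) || !file.exists(file)) {
    snpmelt_abort("nearest-neighbor parameter file not found", "io")
  }
  params <- jsonlite::read_json(file, simplifyVector = TRUE)
  .nn_cache[[key]] <- params
  params
}

# Map any 5'->3' doublet to its canonical key in the ten-entry table.
canonical_stack <- function(doublet, stacks) {
  if (doublet %in% names(stacks)) return(doublet)
  rc <- revcomp(doublet)
  if (!rc %in% names(stacks)) {
    snpmelt_abort(sprintf("unknown dinucleotide step '%s'", doublet), "invalid_input")
  }
  rc
}

#' Construct an oligo/template duplex
#'
#' A primer hybridized to its template, with any positions at which the primer
#' differs from the template recorded as mismatches. Concentrations are molar.
#'
#' @param sequence Primer sequence, 5'->3', `ACGT` only.
#' @param mismatch_positions Integer vector of 1-based primer positions that do
#'   not pair with the template (empty for a perfect duplex).
#' @param concentration Total oligo concentration in mol/L (default 200 nM).
#' @param monovalent Monovalent cation (Na+-equivalent) concentration in mol/L
#'   (default 50 mM).
#' @return An object of class `oligo_duplex`.
#' @export
oligo_duplex <- function(sequence, mismatch_positions = integer(),
                         concentration = 2e-7, monovalent = 0.05) {
  check_dna(sequence, "duplex sequence")
  if (nchar(sequence) < 2L) {
    snpmelt_abort("duplex sequence must be at least 2 bases", "invalid_input")
  }
  mismatch_positions <- as.integer(mismatch_positions)
  if (length(mismatch_positions) &&
      (any(mismatch_positions < 1L) || any(mismatch_positions > nchar(sequence)))) {
    snpmelt_abort("mismatch positions outside the primer", "invalid_input")
  }
  if (!is.numeric(concentration) || concentration <= 0 ||
      !is.numeric(monovalent) || monovalent <= 0) {
    snpmelt_abort("concentrations must be positive", "invalid_input")
  }
  structure(
    list(sequence = toupper(sequence),
         mismatch_positions = sort(unique(mismatch_positions)),
         concentration = concentration, monovalent = monovalent),
    class = "oligo_duplex"
  )
}

#' Primer melting temperature (nearest-neighbor model)
#'
#' Computes the duplex Tm from unified NN stacking enthalpies/entropies with
#' terminal initiation terms, a self-complementarity correction, and a
#' monovalent-salt entropy adjustment of 0.368 cal/(mol K) per phosphate pair:
#' \deqn{T_m = \frac{\Delta H}{\Delta S + R \ln(C_T/x)} - 273.15}
#' with \eqn{x = 4} for non-self-complementary duplexes (1 otherwise).
#' Mismatched positions (e.g. a first-cycle allele-specific primer against the
#' unmodified template) subtract a fixed destabilization penalty per mismatch;
#' full mismatch NN tables are deliberately out of scope since design only
#' needs ranking and threshold behavior.
#'
#' @param duplex An [oligo_duplex()], or a plain DNA string (treated as a
#'   perfectly matched duplex at the default concentrations).
#' @param params NN parameter list from [load_nn_params()].
#' @param mismatch_penalty Tm penalty in degrees C per mismatch (default 5).
#' @return Tm in degrees C, rounded to 0.01.
#' @examples
#' primer_tm("TAGGCTCCTCGCGACTGCTG")
#' @export
primer_tm <- function(duplex, params = load_nn_params(), mismatch_penalty = 5) {
  if (is.character(duplex)) duplex <- oligo_duplex(duplex)
  if (!inherits(duplex, "oligo_duplex")) {
    snpmelt_abort("`duplex` must be an oligo_duplex or a DNA string", "invalid_input")
  }
  s <- duplex$sequence
  n <- nchar(s)
  ch <- seq_chars(s)

  dH <- 0
  dS <- 0
  for (i in seq_len(n - 1L)) {
    key <- canonical_stack(paste0(ch[i], ch[i + 1L]), params$stacks)
    dH <- dH + params$stacks[[key]]$dH
    dS <- dS + params$stacks[[key]]$dS
  }
  for (term in c(ch[1L], ch[n])) {
    init <- if (is_strong(term)) params$initiation$GC else params$initiation$AT
    dH <- dH + init$dH
    dS <- dS + init$dS
  }
  self_comp <- identical(s, revcomp(s))
  x <- 4
  if (self_comp) {
    dS <- dS + params$symmetry$dS
    dH <- dH + params$symmetry$dH
    x <- 1
  }
  dS <- dS + params$salt_dS_per_phosphate_pair * (n - 1L) * log(duplex$monovalent)

  tm_k <- dH * 1000 / (dS + params$gas_constant * log(duplex$concentration / x))
  tm <- tm_k - 273.15 - mismatch_penalty * length(duplex$mismatch_positions)
  round(tm, 2)
}

#' Amplicon melting temperature (GC/length model)
#'
#' Empirical product-melting model used to predict how the deliberate primer
#' mutations separate the two allele amplicons on a melt curve:
#' \deqn{T_m = 81.5 + 16.6\log_{10}[\mathrm{Na}^+] + 41\,f_{GC} - 500/L}
#' Introduced mutations are treated as fully incorporated (the product carries
#' them as matched base pairs from cycle 2 onward), so the input is the final
#' product sequence. Strictly increasing in GC fraction at fixed length;
#' invariant under A<->T and G<->C swaps.
#'
#' @param sequence Amplicon (product) sequence, `ACGT`.
#' @param monovalent Monovalent salt in mol/L (default 50 mM).
#' @return Predicted Tm in degrees C, rounded to 0.01.
#' @export
amplicon_tm <- function(sequence, monovalent = 0.05) {
  check_dna(sequence, "amplicon sequence")
  if (!is.numeric(monovalent) || monovalent <= 0) {
    snpmelt_abort("monovalent salt must be positive", "invalid_input")
  }
  n <- nchar(sequence)
  tm <- 81.5 + 16.6 * log10(monovalent) + 41 * gc_fraction(sequence) - 500 / n
  round(tm, 2)
}
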