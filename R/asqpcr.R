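# Allele-specific qPCR (AS-qPCR) genotype calling.
#
# Each sample is run in two reactions, one per allele-specific primer, and
# the quantification cycle (Cq) of each reaction decides allele presence:
# a reaction crossing threshold before the Cq cutoff (default 30 cycles,
# strict `<`) is positive for its allele. Both positive -> heterozygous;
# one positive -> homozygous for that allele; neither -> no call.

#' Compute the quantification cycle (Cq) of an amplification curve
#'
#' Fits a straight baseline over the configured early-cycle window and finds
#' the fractional cycle at which fluorescence first crosses the threshold by
#' linear interpolation between neighboring cycles. With `threshold = NULL`
#' the threshold is automatic: 10 standard deviations of the baseline-fit
#' residuals, applied to the baseline-corrected signal. A fixed `threshold`
#' is applied to the raw signal instead (use this when the instrument's
#' manual threshold is known, and for noise-free synthetic curves whose
#' baseline residual variance is zero).
#'
#' @param curve Data frame with columns `cycle` (strictly increasing
#'   integers) and `fluorescence`; at least 20 cycles.
#' @param baseline_window Two-element cycle range for the baseline fit
#'   (default cycles 3-15).
#' @param threshold Fixed fluorescence threshold, or `NULL` for automatic.
#' @return A list of class `cq_result`: `cq` (fractional cycle, or `NA` when
#'   the curve never crosses), `threshold_used`, `baseline_window`.
#' @export
compute_cq <- function(curve, baseline_window = c(3, 15), threshold = NULL) {
  stopifnot(is.data.frame(curve), all(c("cycle", "fluorescence") %in% names(curve)))
  cyc <- curve$cycle
  if (is.unsorted(cyc, strictly = TRUE)) {
    snpmelt_abort("cycles must be strictly increasing", "invalid_input")
  }
  if (length(cyc) < 20L) {
    snpmelt_abort("need at least 20 cycles of data", "invalid_input")
  }
  f <- curve$fluorescence

  if (is.null(threshold)) {
    inb <- cyc >= baseline_window[1] & cyc <= baseline_window[2]
    if (sum(inb) < 3L) {
      snpmelt_abort("baseline window covers fewer than 3 cycles", "invalid_input")
    }
    fit <- stats::lm(f[inb] ~ cyc[inb])
    base_sd <- stats::sd(stats::residuals(fit))
    if (!is.finite(base_sd) || base_sd < 1e-9 * max(1, abs(mean(f[inb])))) {
      snpmelt_abort("baseline has zero residual variance; cannot set an automatic threshold",
                    "degenerate_curve")
    }
    base_line <- stats::coef(fit)[1] + stats::coef(fit)[2] * cyc
    signal <- f - base_line
    thr <- 10 * base_sd
  } else {
    signal <- f
    thr <- threshold
  }

  cq <- NA_real_
  for (i in seq_along(cyc)[-1]) {
    if (signal[i] >= thr && signal[i - 1L] < thr) {
      cq <- cyc[i - 1L] + (thr - signal[i - 1L]) / (signal[i] - signal[i - 1L]) *
        (cyc[i] - cyc[i - 1L])
      break
    }
  }
  structure(list(cq = unname(cq), threshold_used = unname(thr),
                 baseline_window = baseline_window),
            class = "cq_result")
}

cq_value <- function(x) {
  if (inherits(x, "cq_result")) x$cq
  else if (is.null(x)) NA_real_
  else if (length(x) == 1L && is.na(x)) NA_real_
  else if (is.numeric(x) && length(x) == 1L) unname(x)
  else snpmelt_abort("Cq must be a cq_result, a number, or NA", "invalid_input")
}

#' Call a genotype from a pair of allele-specific Cq values
#'
#' A reaction is positive for its allele when `Cq < cutoff` (strictly; a Cq
#' of exactly `cutoff` or an absent Cq is not positive). Both positive ->
#' `het`; only the wild-type reaction -> `hom_ref`; only the mutant reaction
#' -> `hom_alt`; neither -> `no_call`. Confidence is the smaller distance of
#' the two Cqs from the cutoff, scaled to `[0, 1]` over 5 cycles (an absent
#' Cq counts as maximally far).
#'
#' @param cq_wild,cq_mut [compute_cq()] results (or bare numbers, `NA` for
#'   no amplification) for the wild-type-specific and mutant-specific
#'   reactions of the same sample.
#' @param cutoff Positivity cutoff in cycles (default 30; chosen empirically
#'   on the instrument and exposed as a parameter for that reason).
#' @return One-row tibble: `call`, `confidence`, `cq_wild`, `cq_mut`.
#' @export
call_genotype_asqpcr <- function(cq_wild, cq_mut, cutoff = 30) {
  qw <- cq_value(cq_wild)
  qm <- cq_value(cq_mut)
  pos_w <- is.finite(qw) && qw < cutoff
  pos_m <- is.finite(qm) && qm < cutoff
  call <- if (pos_w && pos_m) "het"
          else if (pos_w) "hom_ref"
          else if (pos_m) "hom_alt"
          else "no_call"
  margin <- function(q) if (is.finite(q)) abs(cutoff - q) else cutoff
  confidence <- if (call == "no_call") NA_real_
                else clamp(min(margin(qw), margin(qm)) / 5, 0, 1)
  tibble::tibble(call = call, confidence = confidence,
                 cq_wild = qw, cq_mut = qm)
}

#' Call genotypes for an AS-qPCR plate
#'
#' Plate-level driver: computes a Cq for every well (sample x replicate x
#' allele primer), applies the dual-reaction rule per replicate, and merges
#' duplicates (disagreement -> `no_call`).
#'
#' @param plate Long-format tibble: `well`, `sample_id`, `replicate`,
#'   `allele_primer` (`"wild"` or `"mutant"`), `cycle`, `fluorescence`.
#' @param manifest Tibble with `well`, `sample_id`, `role`; only
#'   `role == "sample"` wells are called.
#' @param rsid Locus identifier stamped into the calls.
#' @param cutoff Cq positivity cutoff (default 30).
#' @param threshold Fluorescence threshold passed to [compute_cq()].
#' @param baseline_window Baseline window passed to [compute_cq()].
#' @return Calls tibble: `sample_id`, `rsid`, `call`, `method`, `confidence`,
#'   `replicate_concordant`.
#' @export
call_qpcr_plate <- function(plate, manifest, rsid, cutoff = 30,
                            threshold = 50, baseline_window = c(3, 15)) {
  stopifnot(all(c("well", "sample_id", "replicate", "allele_primer",
                  "cycle", "fluorescence") %in% names(plate)))
  missing_wells <- setdiff(manifest$well, unique(plate$well))
  if (length(missing_wells)) {
    snpmelt_abort(sprintf("manifest references wells absent from the plate: %s",
                          paste(missing_wells, collapse = ", ")), "invalid_input")
  }
  sample_ids <- manifest$sample_id[manifest$role == "sample"]

  cqs <- plate |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::arrange(.data$well, .data$cycle) |>
    dplyr::group_by(.data$sample_id, .data$replicate, .data$allele_primer) |>
    dplyr::summarise(
      cq = compute_cq(dplyr::pick(dplyr::everything()), baseline_window, threshold)$cq,
      .groups = "drop"
    )

  wide <- tidyr::pivot_wider(cqs, names_from = "allele_primer", values_from = "cq")
  if (!all(c("wild", "mutant") %in% names(wide))) {
    snpmelt_abort("every sample needs both a wild and a mutant allele-specific reaction",
                  "invalid_input")
  }
  per_rep <- wide |>
    dplyr::rowwise() |>
    dplyr::mutate(call_genotype_asqpcr(.data$wild, .data$mutant, cutoff)[, c("call", "confidence")]) |>
    dplyr::ungroup()

  merge_replicates(per_rep, rsid, method = "AS-qPCR")
}
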