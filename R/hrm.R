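# High-resolution melt (HRM) genotype calling.
#
# Raw melt curves are normalized between a pre-melt and a post-melt window
# (line fits in each window define the 100% and 0% fluorescence levels at
# every temperature) and classified by mean-squared distance against
# normalized curves of known-genotype control samples run on the same plate.
# The commercial melt-analysis algorithm used on the instrument is
# proprietary; nearest-reference classification is a transparent surrogate
# that is justified operationally because every run carries sequencing-
# confirmed controls of all three genotypes.

melt_validate <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("temperature", "fluorescence") %in% names(curve)))
  tt <- curve$temperature
  if (is.unsorted(tt, strictly = TRUE)) {
    snpmelt_abort("temperatures must be strictly increasing", "invalid_input")
  }
  if (any(!is.finite(curve$fluorescence))) {
    snpmelt_abort("fluorescence contains non-finite values", "invalid_input")
  }
  invisible(curve)
}

window_line <- function(curve, window, what) {
  inside <- curve$temperature >= window[1] & curve$temperature <= window[2]
  if (sum(inside) < 3L) {
    snpmelt_abort(sprintf("%s window [%g, %g] contains fewer than 3 points",
                          what, window[1], window[2]), "invalid_input")
  }
  fit <- stats::lm(fluorescence ~ temperature, data = curve[inside, ])
  unname(stats::predict(fit, newdata = curve["temperature"]))
}

#' Normalize a raw melt curve
#'
#' Fits a line to the fluorescence in a pre-melt window (fully double-
#' stranded) and in a post-melt window (fully melted), then rescales every
#' point as `(F - post_line) / (pre_line - post_line)`, clipped to `[0, 1]`.
#' Per-well gain and additive offset (including a linear baseline drift)
#' cancel exactly, so curves from different wells become comparable;
#' re-normalizing an already-normalized curve with the same windows is a
#' no-op.
#'
#' @param curve Data frame with columns `temperature` (strictly increasing,
#'   degrees C) and `fluorescence`.
#' @param pre_window,post_window Two-element `(low, high)` temperature
#'   windows; `pre_window` must lie below `post_window` and both inside the
#'   measured range, each covering at least 3 points.
#' @return A tibble with columns `temperature` and `normalized`, carrying the
#'   windows in attribute `windows`.
#' @export
normalize_melt <- function(curve, pre_window = c(72, 76), post_window = c(90, 94)) {
  melt_validate(curve)
  if (pre_window[1] >= pre_window[2] || post_window[1] >= post_window[2] ||
      pre_window[2] >= post_window[1]) {
    snpmelt_abort("windows must be ordered, non-overlapping, pre below post",
                  "invalid_input")
  }
  rng <- range(curve$temperature)
  if (pre_window[1] < rng[1] || post_window[2] > rng[2]) {
    snpmelt_abort("normalization windows fall outside the measured range",
                  "invalid_input")
  }
  pre_line <- window_line(curve, pre_window, "pre-melt")
  post_line <- window_line(curve, post_window, "post-melt")
  denom <- pre_line - post_line
  if (all(denom <= 0)) {
    snpmelt_abort("pre-melt level does not exceed post-melt level anywhere; degenerate curve",
                  "degenerate_curve")
  }
  norm <- clamp((curve$fluorescence - post_line) / denom, 0, 1)
  out <- tibble::tibble(temperature = curve$temperature, normalized = norm)
  attr(out, "windows") <- list(pre = pre_window, post = post_window)
  out
}

#' Resample a normalized curve onto a temperature grid
#'
#' Linear interpolation; the grid must lie inside the measured range.
#'
#' @param curve Tibble with `temperature` and a value column (`normalized` or
#'   `fluorescence`).
#' @param grid Numeric vector of target temperatures.
#' @return Tibble with `temperature` and the interpolated value column.
#' @export
resample_curve <- function(curve, grid) {
  value_col <- intersect(c("normalized", "fluorescence"), names(curve))[1]
  if (is.na(value_col)) {
    snpmelt_abort("curve has no value column to resample", "invalid_input")
  }
  if (min(grid) < min(curve$temperature) - 1e-9 ||
      max(grid) > max(curve$temperature) + 1e-9) {
    snpmelt_abort("resampling grid extends beyond the measured range", "invalid_input")
  }
  y <- stats::approx(curve$temperature, curve[[value_col]], xout = grid,
                     ties = "ordered")$y
  out <- tibble::tibble(temperature = grid, value = y)
  names(out)[2] <- value_col
  out
}

common_grid <- function(curves, step = 0.1) {
  lo <- max(vapply(curves, function(c) min(c$temperature), numeric(1)))
  hi <- min(vapply(curves, function(c) max(c$temperature), numeric(1)))
  if (hi - lo < 5 * step) {
    snpmelt_abort("curve temperature ranges do not overlap enough to align",
                  "invalid_input")
  }
  seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
}

#' Call a genotype from a normalized melt curve
#'
#' Classifies one normalized curve against known-genotype reference curves by
#' mean-squared distance on a shared temperature grid. The call is the
#' nearest reference; `confidence = 1 - d_best / d_second`, so a curve midway
#' between two references scores 0 and an exact match scores 1. Confidence
#' below `ambiguity_ratio` gives `no_call`.
#'
#' @param sample A normalized curve ([normalize_melt()] output).
#' @param references Named list of normalized curves; names must include
#'   `hom_ref`, `het` and `hom_alt`.
#' @param ambiguity_ratio Minimum confidence for a call (default 0.2).
#' @param grid_step Alignment grid spacing in degrees C (default 0.1).
#' @return One-row tibble: `call`, `confidence`, and one distance column per
#'   reference genotype (`d_hom_ref`, `d_het`, `d_hom_alt`).
#' @export
call_genotype_hrm <- function(sample, references, ambiguity_ratio = 0.2,
                              grid_step = 0.1) {
  needed <- c("hom_ref", "het", "hom_alt")
  if (!all(needed %in% names(references))) {
    snpmelt_abort(sprintf("references must include %s", paste(needed, collapse = ", ")),
                  "invalid_input")
  }
  references <- references[needed]
  grid <- common_grid(c(list(sample), references), step = grid_step)
  sv <- resample_curve(sample, grid)$normalized
  d <- vapply(references, function(r) {
    rv <- resample_curve(r, grid)$normalized
    mean((sv - rv)^2)
  }, numeric(1))

  ord <- order(d)
  best <- d[ord[1]]; second <- d[ord[2]]
  confidence <- if (second <= 0) {
    if (best <= 0) 0 else NA_real_  # two identical references: unclassifiable
  } else 1 - best / second
  call <- names(d)[ord[1]]
  if (!is.finite(confidence) || confidence < ambiguity_ratio) {
    call <- "no_call"
    confidence <- NA_real_
  }
  out <- tibble::tibble(call = call, confidence = confidence)
  dn <- tibble::as_tibble(as.list(stats::setNames(d, paste0("d_", names(d)))))
  dplyr::bind_cols(out, dn)
}

#' Difference curve between a sample and a reference
#'
#' Pointwise signed residual `sample - reference`, the standard HRM
#' visualization for separating genotype clusters. Grids must match exactly.
#'
#' @param sample,reference Normalized curves on the same temperature grid.
#' @return Tibble with `temperature` and `residual`.
#' @export
difference_curve <- function(sample, reference) {
  if (nrow(sample) != nrow(reference) ||
      max(abs(sample$temperature - reference$temperature)) > 1e-9) {
    snpmelt_abort("sample and reference grids are not aligned", "invalid_input")
  }
  tibble::tibble(temperature = sample$temperature,
                 residual = sample$normalized - reference$normalized)
}

#' Call genotypes for an HRM plate
#'
#' Plate-level driver: normalizes every well, builds the three reference
#' curves by averaging the replicate wells of the known-genotype controls in
#' the manifest, classifies each sample replicate, and merges duplicates.
#' Duplicate wells must agree; disagreement (or any replicate no_call) yields
#' `no_call` with `replicate_concordant = FALSE` when the replicates named
#' different genotypes.
#'
#' @param plate Long-format tibble: `well`, `sample_id`, `replicate`,
#'   `temperature`, `fluorescence`.
#' @param manifest Tibble mapping wells to samples: `well`, `sample_id`,
#'   `role` (`"sample"` or `"control"`), `genotype` (controls only:
#'   `hom_ref`/`het`/`hom_alt`).
#' @param rsid Locus identifier stamped into the calls.
#' @param pre_window,post_window Normalization windows (see
#'   [normalize_melt()]).
#' @param ambiguity_ratio Minimum per-replicate confidence.
#' @return Calls tibble: `sample_id`, `rsid`, `call`, `method`, `confidence`,
#'   `replicate_concordant`.
#' @export
call_hrm_plate <- function(plate, manifest, rsid,
                           pre_window = c(72, 76), post_window = c(90, 94),
                           ambiguity_ratio = 0.2) {
  stopifnot(all(c("well", "sample_id", "replicate", "temperature", "fluorescence")
                %in% names(plate)),
            all(c("well", "sample_id", "role") %in% names(manifest)))
  missing_wells <- setdiff(manifest$well, unique(plate$well))
  if (length(missing_wells)) {
    snpmelt_abort(sprintf("manifest references wells absent from the plate: %s",
                          paste(missing_wells, collapse = ", ")), "invalid_input")
  }

  normalized <- plate |>
    dplyr::arrange(.data$well, .data$temperature) |>
    dplyr::group_by(.data$well, .data$sample_id, .data$replicate) |>
    dplyr::group_modify(~ normalize_melt(.x, pre_window, post_window)) |>
    dplyr::ungroup()

  ctrl <- manifest |> dplyr::filter(.data$role == "control")
  if (!all(c("hom_ref", "het", "hom_alt") %in% ctrl$genotype)) {
    snpmelt_abort("manifest must provide control wells for all three genotypes",
                  "invalid_input")
  }
  ctrl_curves <- normalized |>
    dplyr::inner_join(ctrl[, c("well", "genotype")], by = "well")
  grid <- common_grid(split(ctrl_curves[, c("temperature", "normalized")],
                            ctrl_curves$well))
  references <- purrr::map(split(ctrl_curves, ctrl_curves$genotype), function(g) {
    reps <- purrr::map(split(g, g$well), ~ resample_curve(.x, grid)$normalized)
    tibble::tibble(temperature = grid,
                   normalized = Reduce(`+`, reps) / length(reps))
  })

  sample_wells <- manifest |> dplyr::filter(.data$role == "sample")
  per_rep <- normalized |>
    dplyr::semi_join(sample_wells, by = "well") |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_modify(~ call_genotype_hrm(.x, references, ambiguity_ratio)) |>
    dplyr::ungroup()

  merge_replicates(per_rep, rsid, method = "HRM")
}

# Combine per-replicate calls for each sample: duplicates must name the same
# genotype, otherwise (or when any replicate is no_call) the sample is no_call.
merge_replicates <- function(per_rep, rsid, method) {
  per_rep |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      replicate_concordant = dplyr::n_distinct(.data$call) == 1L,
      ok = dplyr::n_distinct(.data$call) == 1L && .data$call[1] != "no_call",
      call = if (dplyr::n_distinct(.data$call) == 1L) .data$call[1] else "no_call",
      confidence = suppressWarnings(min(.data$confidence)),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      sample_id = .data$sample_id, rsid = rsid,
      call = ifelse(.data$ok, .data$call, "no_call"),
      method = method,
      confidence = ifelse(.data$ok, .data$confidence, NA_real_),
      replicate_concordant = .data$replicate_concordant
    )
}

#' Recommended normalization windows for an assay
#'
#' The pre-melt window must sit below both allele amplicons' transitions and
#' the post-melt window above them. Given a designed triplet this derives
#' per-assay windows from the predicted amplicon Tms (default margins: window
#' of 4 degrees C ending 5 degrees C below the cooler transition, and
#' starting 5 degrees C above the hotter one).
#'
#' @param triplet A `primer_triplet` (or list with `amplicon_tms`).
#' @param margin Distance in degrees C between a transition and the nearer
#'   window edge.
#' @param width Window width in degrees C.
#' @return List with elements `pre` and `post`, each `(low, high)`.
#' @export
hrm_windows <- function(triplet, margin = 5, width = 4) {
  tms <- triplet$amplicon_tms
  if (is.null(tms) || anyNA(tms)) {
    snpmelt_abort("triplet has no predicted amplicon Tms", "invalid_input")
  }
  lo <- min(tms); hi <- max(tms)
  list(pre = c(lo - margin - width, lo - margin),
       post = c(hi + margin, hi + margin + width))
}
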