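# Synthetic cohorts and instrument-like fluorescence traces.
#
# The generator emulates the structure of a case-control genotyping study:
# genotypes drawn per group from specified frequencies, each sample run in
# duplicate wells, melt curves as two-state (homozygote) or equal-weight
# mixture (heterozygote) helix-coil transitions at the allele amplicons'
# predicted Tms, and amplification curves as logistic growth whose Cq
# reflects allele presence. Fluorescence units are arbitrary (0-1000 scale);
# only curve shape carries information. Everything is reproducible from a
# seed, with per-well gain, linear baseline drift, and additive Gaussian
# noise as the imperfections.

#' Cohort specification
#'
#' @param n_cases,n_controls Group sizes (defaults 55 cases, 110 controls,
#'   the 1:2 case-control design the bundled example tables come from).
#' @param freq_cases,freq_controls Genotype frequency vectors, named
#'   `hom_ref`, `het`, `hom_alt`, each summing to 1.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 55L, n_controls = 110L,
                        freq_cases = c(hom_ref = 1/3, het = 1/3, hom_alt = 1/3),
                        freq_controls = c(hom_ref = 1/3, het = 1/3, hom_alt = 1/3)) {
  for (f in list(freq_cases, freq_controls)) {
    if (!all(c("hom_ref", "het", "hom_alt") %in% names(f)) ||
        any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      snpmelt_abort("genotype frequencies must be named hom_ref/het/hom_alt, non-negative, summing to 1",
                    "invalid_input")
    }
  }
  stopifnot(n_cases >= 1L, n_controls >= 1L)
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 freq_cases = freq_cases[c("hom_ref", "het", "hom_alt")],
                 freq_controls = freq_controls[c("hom_ref", "het", "hom_alt")]),
            class = "cohort_spec")
}

#' Curve noise model
#'
#' Imperfections applied to simulated traces. Defaults: additive noise of
#' 0.5% of the plateau, per-well gain within +-10%, baseline drift up to
#' 0.1% of the plateau per degree C, a 0.5 degree C melt transition width,
#' amplification efficiency 0.85-1, and a 2% chance of late nonspecific
#' amplification in allele-absent reactions.
#'
#' @param noise_sd Additive noise SD as a fraction of the plateau.
#' @param gain_range Per-well multiplicative gain range.
#' @param drift_range Baseline drift slope range, fraction of plateau per
#'   degree C (melts) or per cycle (amplification).
#' @param transition_width Melt transition width in degrees C.
#' @param efficiency_range Per-reaction amplification efficiency range,
#'   within `(0, 1]`.
#' @param nonspecific_prob Probability that an allele-absent reaction shows
#'   late (Cq > 32) nonspecific amplification.
#' @return A list of class `curve_noise_model`.
#' @export
curve_noise_model <- function(noise_sd = 0.005, gain_range = c(0.9, 1.1),
                              drift_range = c(-0.001, 0.001),
                              transition_width = 0.5,
                              efficiency_range = c(0.85, 1),
                              nonspecific_prob = 0.02) {
  stopifnot(noise_sd >= 0, all(gain_range > 0), transition_width > 0,
            all(efficiency_range > 0), all(efficiency_range <= 1),
            nonspecific_prob >= 0, nonspecific_prob <= 1)
  structure(list(noise_sd = noise_sd, gain_range = gain_range,
                 drift_range = drift_range, transition_width = transition_width,
                 efficiency_range = efficiency_range,
                 nonspecific_prob = nonspecific_prob),
            class = "curve_noise_model")
}

noiseless <- function() {
  curve_noise_model(noise_sd = 0, gain_range = c(1, 1), drift_range = c(0, 0),
                    efficiency_range = c(0.95, 0.95), nonspecific_prob = 0)
}

#' Simulate genotype assignments for a case-control cohort
#'
#' Independent multinomial draws per group at the specified genotype
#' frequencies; identical seeds give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Tibble: `sample_id`, `group` (`"case"`/`"control"`), `genotype`.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  genos <- c("hom_ref", "het", "hom_alt")
  withr::with_seed(seed, {
    g_case <- sample(genos, spec$n_cases, replace = TRUE, prob = spec$freq_cases)
    g_ctrl <- sample(genos, spec$n_controls, replace = TRUE, prob = spec$freq_controls)
  })
  tibble::tibble(
    sample_id = c(sprintf("case_%03d", seq_len(spec$n_cases)),
                  sprintf("ctrl_%03d", seq_len(spec$n_controls))),
    group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
    genotype = c(g_case, g_ctrl)
  )
}

# Helix fraction of a two-state transition centered at tm.
helix_fraction <- function(temp, tm, width) 1 / (1 + exp((temp - tm) / width))

melt_weights <- function(genotype) {
  switch(genotype,
         hom_ref = c(wild = 1, mutant = 0),
         het = c(wild = 0.5, mutant = 0.5),
         hom_alt = c(wild = 0, mutant = 1),
         snpmelt_abort(sprintf("unknown genotype '%s'", genotype), "invalid_input"))
}

#' Simulate duplicate melt curves for one sample
#'
#' Homozygotes melt in a single transition at their allele amplicon's
#' predicted Tm; heterozygotes are an equal-weight mixture of the two
#' transitions (the allele products differ in composition, and both amplify
#' in a heterozygote). Per-well gain, linear drift and additive noise are
#' applied independently to each replicate well.
#'
#' @param genotype `"hom_ref"`, `"het"` or `"hom_alt"`.
#' @param triplet A `primer_triplet` supplying the allele amplicon Tms (any
#'   list with an `amplicon_tms` element named `wild`/`mutant` works).
#' @param noise A [curve_noise_model()].
#' @param seed Integer seed.
#' @param n_replicates Number of replicate wells (default 2).
#' @param temperatures Acquisition grid, degrees C (default 50-95 by 0.1).
#' @param plateau,background Fluorescence levels of fully double-stranded and
#'   fully melted product (arbitrary units).
#' @return Long tibble: `replicate`, `temperature`, `fluorescence`.
#' @export
simulate_melt <- function(genotype, triplet, noise = curve_noise_model(),
                          seed = 1L, n_replicates = 2L,
                          temperatures = seq(50, 95, by = 0.1),
                          plateau = 1000, background = 30) {
  w <- melt_weights(genotype)
  tms <- triplet$amplicon_tms
  if (is.null(tms) || !all(c("wild", "mutant") %in% names(tms)) || anyNA(tms)) {
    snpmelt_abort("triplet has no predicted allele amplicon Tms", "invalid_input")
  }
  shape <- w[["wild"]] * helix_fraction(temperatures, tms[["wild"]], noise$transition_width) +
    w[["mutant"]] * helix_fraction(temperatures, tms[["mutant"]], noise$transition_width)
  clean <- background + (plateau - background) * shape
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(rep) {
      gain <- stats::runif(1, noise$gain_range[1], noise$gain_range[2])
      drift <- stats::runif(1, noise$drift_range[1], noise$drift_range[2])
      f <- gain * clean + plateau * drift * (temperatures - temperatures[1]) +
        stats::rnorm(length(temperatures), 0, noise$noise_sd * plateau)
      tibble::tibble(replicate = rep, temperature = temperatures, fluorescence = f)
    })
  })
}

#' Simulate duplicate amplification curves for one reaction
#'
#' Logistic growth crossing a nominal threshold of 50 fluorescence units at a
#' target Cq drawn uniformly in 24-27 cycles when the targeted allele is
#' present (heterozygotes start from half the template, costing one doubling
#' time); allele-absent reactions stay flat except for occasional nonspecific
#' amplification with Cq above 32. Halving the template copies raises Cq by
#' one doubling time (`1/log2(1 + efficiency)` cycles).
#'
#' @param genotype `"hom_ref"`, `"het"` or `"hom_alt"`.
#' @param allele_primer `"wild"` or `"mutant"`: which allele-specific
#'   reaction this is.
#' @param noise A [curve_noise_model()].
#' @param seed Integer seed.
#' @param n_replicates Number of replicate wells (default 2).
#' @param cycles Cycle vector (default 1:40).
#' @param template_copies Relative template input; the default 1 is the
#'   calibration at which present-allele Cq falls in 24-27.
#' @param plateau Plateau fluorescence (arbitrary units).
#' @return Long tibble: `replicate`, `cycle`, `fluorescence`.
#' @export
simulate_amplification <- function(genotype, allele_primer = c("wild", "mutant"),
                                   noise = curve_noise_model(), seed = 1L,
                                   n_replicates = 2L, cycles = 1:40,
                                   template_copies = 1, plateau = 1000) {
  allele_primer <- match.arg(allele_primer)
  w <- melt_weights(genotype)
  dose <- w[[allele_primer]]          # fraction of template carrying the allele
  thr_nominal <- 50
  withr::with_seed(seed, {
    eff <- stats::runif(1, noise$efficiency_range[1], noise$efficiency_range[2])
    rate <- log(1 + eff)
    present <- dose > 0 && template_copies > 0
    late <- !present && stats::runif(1) < noise$nonspecific_prob
    target_cq <- if (present) {
      stats::runif(1, 24, 27) + log2(1 / (dose * template_copies)) / log2(1 + eff)
    } else if (late) {
      stats::runif(1, 33, 38)
    } else NA_real_
    purrr::map_dfr(seq_len(n_replicates), function(rep) {
      gain <- stats::runif(1, noise$gain_range[1], noise$gain_range[2])
      drift <- stats::runif(1, noise$drift_range[1], noise$drift_range[2])
      f <- plateau * drift * cycles +
        stats::rnorm(length(cycles), 0, noise$noise_sd * plateau)
      if (!is.na(target_cq)) {
        cq_rep <- target_cq + stats::rnorm(1, 0, 0.1 * (noise$noise_sd > 0))
        # place the logistic so the clean curve crosses thr_nominal at cq_rep
        c0 <- cq_rep + log(plateau / thr_nominal - 1) / rate
        f <- f + gain * plateau / (1 + exp(-rate * (cycles - c0)))
      }
      tibble::tibble(replicate = rep, cycle = cycles, fluorescence = f)
    })
  })
}

#' Simulate a full genotyping experiment
#'
#' Draws a cohort, adds three known-genotype control samples, and emits the
#' plate files the callers read: a melt plate and an AS-qPCR plate (each
#' sample in duplicate wells) plus the well manifest and the true genotypes.
#'
#' @param spec A [cohort_spec()].
#' @param triplet A `primer_triplet` (or any list with `amplicon_tms`).
#' @param noise A [curve_noise_model()].
#' @param seed Integer seed driving the cohort and every curve.
#' @param what Which plates to generate: `"melt"`, `"qpcr"` or both.
#' @param cohort Optional pre-built cohort tibble (`sample_id`, `group`,
#'   `genotype`) replacing the multinomial draw, e.g. for balanced designs.
#' @return List with `cohort` (truth), `manifest`, `qpcr_manifest`, and
#'   tibbles `melt_plate` and/or `qpcr_plate`.
#' @export
simulate_experiment <- function(spec, triplet, noise = curve_noise_model(),
                                seed = 1L, what = c("melt", "qpcr"),
                                cohort = NULL) {
  what <- match.arg(what, several.ok = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(spec, seed = seed)
  controls <- tibble::tibble(
    sample_id = paste0("control_", c("hom_ref", "het", "hom_alt")),
    group = "control_sample",
    genotype = c("hom_ref", "het", "hom_alt")
  )
  all_samples <- dplyr::bind_rows(controls, cohort)
  n <- nrow(all_samples)

  manifest <- tibble::tibble(
    well = new_well_ids(2L * n),
    sample_id = rep(all_samples$sample_id, each = 2L),
    replicate = rep(1:2, n),
    role = rep(ifelse(all_samples$group == "control_sample", "control", "sample"),
               each = 2L),
    genotype = rep(ifelse(all_samples$group == "control_sample",
                          all_samples$genotype, NA_character_), each = 2L)
  )

  out <- list(cohort = cohort, manifest = manifest)

  if ("melt" %in% what) {
    out$melt_plate <- purrr::map_dfr(seq_len(n), function(i) {
      simulate_melt(all_samples$genotype[i], triplet, noise,
                    seed = seed + 7L * i) |>
        dplyr::mutate(sample_id = all_samples$sample_id[i]) |>
        dplyr::left_join(manifest[, c("well", "sample_id", "replicate")],
                         by = c("sample_id", "replicate")) |>
        dplyr::select("well", "sample_id", "replicate", "temperature", "fluorescence")
    })
  }
  if ("qpcr" %in% what) {
    # AS-qPCR splits each sample into separate wells per allele primer
    out$qpcr_manifest <- manifest |>
      tidyr::expand_grid(allele_primer = c("wild", "mutant")) |>
      dplyr::mutate(well = paste0(.data$well, "_", substr(.data$allele_primer, 1, 1)))
    out$qpcr_plate <- purrr::map_dfr(seq_len(n), function(i) {
      purrr::map_dfr(c("wild", "mutant"), function(ap) {
        simulate_amplification(all_samples$genotype[i], ap, noise,
                               seed = seed + 13L * i + (ap == "mutant")) |>
          dplyr::mutate(sample_id = all_samples$sample_id[i], allele_primer = ap)
      })
    }) |>
      dplyr::left_join(out$qpcr_manifest[, c("well", "sample_id", "replicate", "allele_primer")],
                       by = c("sample_id", "replicate", "allele_primer")) |>
      dplyr::select("well", "sample_id", "replicate", "allele_primer",
                    "cycle", "fluorescence")
  }
  out
}
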