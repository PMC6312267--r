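# Fixtures are generated in code: random targets with controlled GC content,
# one cached deterministic demo assay, and idealized curve builders used as
# oracles.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

make_target <- function(seed, ref = "C", alt = "T", gc = 0.55, flank = 120) {
  withr::with_seed(seed, {
    snp_target(paste0("rs_fix", seed), random_dna(flank, gc), random_dna(flank, gc),
               ref, alt)
  })
}

.fixtures <- new.env()

demo_target <- function() {
  if (is.null(.fixtures$target)) .fixtures$target <- make_target(101)
  .fixtures$target
}

demo_triplet <- function() {
  if (is.null(.fixtures$triplet)) .fixtures$triplet <- design_triplet(demo_target())
  .fixtures$triplet
}

zero_noise <- function() {
  curve_noise_model(noise_sd = 0, gain_range = c(1, 1), drift_range = c(0, 0),
                    efficiency_range = c(0.95, 0.95), nonspecific_prob = 0)
}

# Idealized two-state (or mixture) melt curve with exact sigmoid shape.
sigmoid_melt <- function(tms, weights = rep(1 / length(tms), length(tms)),
                         temperatures = seq(50, 95, by = 0.1),
                         top = 1000, bottom = 100, width = 0.5) {
  h <- Reduce(`+`, Map(function(tm, w) w / (1 + exp((temperatures - tm) / width)),
                       tms, weights))
  tibble::tibble(temperature = temperatures, fluorescence = bottom + (top - bottom) * h)
}

# Piecewise-linear melt: exactly flat plateaus, exactly linear transition.
plateau_melt <- function(t_lo = 80, t_hi = 88, temperatures = seq(50, 95, by = 0.1),
                         top = 1, bottom = 0) {
  f <- ifelse(temperatures <= t_lo, top,
              ifelse(temperatures >= t_hi, bottom,
                     top + (bottom - top) * (temperatures - t_lo) / (t_hi - t_lo)))
  tibble::tibble(temperature = temperatures, fluorescence = f)
}

noiseless_logistic <- function(midpoint = 24, rate = 1.2, plateau = 1000,
                               cycles = 1:40) {
  tibble::tibble(cycle = cycles,
                 fluorescence = plateau / (1 + exp(-rate * (cycles - midpoint))))
}
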