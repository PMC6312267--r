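# Melt-curve normalization and nearest-reference genotype calling.

test_that("normalization maps flat plateaus to 1 and 0", {
  curve <- sigmoid_melt(84, 1, top = 1000, bottom = 100)
  norm <- normalize_melt(curve)
  pre <- norm$normalized[norm$temperature >= 72 & norm$temperature <= 76]
  post <- norm$normalized[norm$temperature >= 90 & norm$temperature <= 94]
  expect_equal(mean(pre), 1, tolerance = 1e-6)
  expect_equal(mean(post), 0, tolerance = 1e-6)
  expect_true(all(norm$normalized >= 0 & norm$normalized <= 1))
})

test_that("normalization is idempotent", {
  curve <- plateau_melt()
  n1 <- normalize_melt(curve)
  n2 <- normalize_melt(dplyr::rename(n1, fluorescence = normalized))
  expect_equal(n2$normalized, n1$normalized, tolerance = 1e-9)
})

test_that("normalized mixture curve matches the closed-form mixture value", {
  # equal-weight mixture of transitions at 80 and 84 degrees C
  curve <- sigmoid_melt(c(80, 84), c(0.5, 0.5))
  norm <- normalize_melt(curve, pre_window = c(70, 74), post_window = c(90, 94))
  at <- function(T) norm$normalized[which.min(abs(norm$temperature - T))]
  h <- function(T, tm) 1 / (1 + exp((T - tm) / 0.5))
  expect_equal(at(81.5), 0.5 * h(81.5, 80) + 0.5 * h(81.5, 84), tolerance = 1e-3)
  expect_equal(at(81.5), 0.520367, tolerance = 1e-3)  # frozen direct evaluation
})

test_that("normalization is invariant to per-well gain, offset and linear drift", {
  curve <- sigmoid_melt(c(80, 84), c(0.5, 0.5))
  withr::with_seed(31, {
    for (i in 1:5) {
      gain <- runif(1, 0.5, 2)
      offset <- runif(1, -200, 200)
      slope <- runif(1, -2, 2)
      warped <- dplyr::mutate(curve,
        fluorescence = gain * fluorescence + offset + slope * (temperature - 50))
      expect_equal(normalize_melt(warped)$normalized,
                   normalize_melt(curve)$normalized, tolerance = 1e-9)
    }
  })
})

test_that("normalization rejects bad windows and degenerate curves", {
  curve <- sigmoid_melt(84, 1)
  expect_error(normalize_melt(curve, c(76, 72), c(90, 94)),
               class = "snpmelt_invalid_input")
  expect_error(normalize_melt(curve, c(72, 76), c(75, 94)),
               class = "snpmelt_invalid_input")
  expect_error(normalize_melt(curve, c(40, 44), c(90, 94)),
               class = "snpmelt_invalid_input")
  # window with too few points
  sparse <- curve[seq(1, nrow(curve), by = 100), ]
  expect_error(normalize_melt(sparse, c(72, 76), c(90, 94)),
               class = "snpmelt_invalid_input")
  # inverted curve: pre level below post level everywhere
  inverted <- dplyr::mutate(curve, fluorescence = -fluorescence)
  expect_error(normalize_melt(inverted), class = "snpmelt_degenerate_curve")
})

make_refs <- function(width = 0.5) {
  list(
    hom_ref = normalize_melt(sigmoid_melt(80, 1, width = width)),
    het = normalize_melt(sigmoid_melt(c(80, 84), c(0.5, 0.5), width = width)),
    hom_alt = normalize_melt(sigmoid_melt(84, 1, width = width))
  )
}

test_that("noiseless curves classify as themselves with full confidence", {
  refs <- make_refs()
  for (g in names(refs)) {
    res <- call_genotype_hrm(refs[[g]], refs)
    expect_identical(res$call, g)
    expect_gt(res$confidence, 0.99)
    expect_equal(res[[paste0("d_", g)]], 0)
  }
})

test_that("a sample equidistant from two references is a no-call", {
  refs <- make_refs()
  # 50/50 mixture of the two homozygote references is equidistant from them
  # only by construction of a symmetric pair; build a curve midway between
  # hom_ref and het instead: weights 0.75/0.25
  mid <- normalize_melt(sigmoid_melt(c(80, 84), c(0.75, 0.25)))
  res <- call_genotype_hrm(mid, refs)
  expect_identical(res$call, "no_call")
  expect_true(is.na(res$confidence))
})

test_that("reference insertion order does not change the call", {
  refs <- make_refs()
  sample <- normalize_melt(sigmoid_melt(c(80, 84), c(0.55, 0.45)))
  r1 <- call_genotype_hrm(sample, refs)
  r2 <- call_genotype_hrm(sample, refs[c("hom_alt", "het", "hom_ref")])
  expect_identical(r1$call, r2$call)
  expect_equal(r1$confidence, r2$confidence)
})

test_that("the classifier requires all three reference genotypes", {
  refs <- make_refs()
  expect_error(call_genotype_hrm(refs$het, refs[c("hom_ref", "het")]),
               class = "snpmelt_invalid_input")
})

test_that("difference curves are zero against self and linear in the sample", {
  refs <- make_refs()
  expect_true(all(difference_curve(refs$het, refs$het)$residual == 0))
  d_alt <- difference_curve(refs$hom_alt, refs$hom_ref)
  # largest divergence between the two homozygotes lies between their Tms
  peak <- d_alt$temperature[which.max(abs(d_alt$residual))]
  expect_gt(peak, 80)
  expect_lt(peak, 84)
  # linearity: integral of (het - hom_ref) equals difference of integrals
  d_het <- difference_curve(refs$het, refs$hom_ref)
  expect_equal(sum(d_het$residual),
               sum(refs$het$normalized) - sum(refs$hom_ref$normalized),
               tolerance = 1e-9)
  # misaligned grids
  shifted <- dplyr::mutate(refs$het, temperature = temperature + 0.05)
  expect_error(difference_curve(shifted, refs$hom_ref),
               class = "snpmelt_invalid_input")
})

test_that("plate calling with duplicate wells is concordant on clean data", {
  tr <- demo_triplet()
  win <- hrm_windows(tr)
  spec <- cohort_spec(20, 20)
  sim <- simulate_experiment(spec, tr, zero_noise(), seed = 3, what = "melt")
  calls <- call_hrm_plate(sim$melt_plate, sim$manifest, tr$rsid, win$pre, win$post)
  joined <- dplyr::inner_join(calls, sim$cohort, by = "sample_id")
  expect_identical(nrow(joined), 40L)
  expect_true(all(joined$call == joined$genotype))
  expect_true(all(joined$replicate_concordant))
  expect_true(all(joined$method == "HRM"))
})

test_that("plate calling flags discordant duplicates as no-calls", {
  tr <- demo_triplet()
  win <- hrm_windows(tr)
  spec <- cohort_spec(4, 4)
  sim <- simulate_experiment(spec, tr, zero_noise(), seed = 4, what = "melt")
  # corrupt one replicate of one sample so its duplicate disagrees
  victim <- sim$cohort$sample_id[1]
  vg <- sim$cohort$genotype[1]
  other <- setdiff(c("hom_ref", "hom_alt"), vg)[1]
  wells <- sim$manifest$well[sim$manifest$sample_id == victim]
  swap <- simulate_melt(other, tr, zero_noise(), seed = 99, n_replicates = 1L)
  idx <- sim$melt_plate$well == wells[2]
  sim$melt_plate$fluorescence[idx] <- swap$fluorescence
  calls <- call_hrm_plate(sim$melt_plate, sim$manifest, tr$rsid, win$pre, win$post)
  row <- calls[calls$sample_id == victim, ]
  expect_identical(row$call, "no_call")
  expect_false(row$replicate_concordant)
})

test_that("a manifest referencing a missing well is a validation error", {
  tr <- demo_triplet()
  spec <- cohort_spec(2, 2)
  sim <- simulate_experiment(spec, tr, zero_noise(), seed = 5, what = "melt")
  bad_manifest <- dplyr::bind_rows(sim$manifest,
    tibble::tibble(well = "9_Z99", sample_id = "ghost", replicate = 1L,
                   role = "sample", genotype = NA_character_))
  expect_error(call_hrm_plate(sim$melt_plate, bad_manifest, tr$rsid),
               class = "snpmelt_invalid_input")
})
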