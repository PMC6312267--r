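# Cohort and fluorescence-trace generators.

test_that("cohort draws are seeded and respect degenerate frequencies", {
  spec <- cohort_spec(50, 100,
                      c(hom_ref = 0.5, het = 0.3, hom_alt = 0.2),
                      c(hom_ref = 0.6, het = 0.3, hom_alt = 0.1))
  a <- simulate_cohort(spec, seed = 9)
  b <- simulate_cohort(spec, seed = 9)
  expect_identical(a, b)
  expect_identical(nrow(a), 150L)

  all_ref <- cohort_spec(30, 30, c(hom_ref = 1, het = 0, hom_alt = 0),
                         c(hom_ref = 1, het = 0, hom_alt = 0))
  expect_true(all(simulate_cohort(all_ref, seed = 1)$genotype == "hom_ref"))

  expect_error(cohort_spec(10, 10, c(hom_ref = 0.5, het = 0.6, hom_alt = 0.1)),
               class = "snpmelt_invalid_input")
})

test_that("empirical genotype frequencies recover the specification", {
  spec <- cohort_spec(5000, 5000,
                      c(hom_ref = 0.364, het = 0.236, hom_alt = 0.4),
                      c(hom_ref = 0.654, het = 0.209, hom_alt = 0.137))
  cohort <- simulate_cohort(spec, seed = 10)
  emp <- prop.table(table(cohort$genotype[cohort$group == "case"]))
  expect_lt(abs(emp[["hom_ref"]] - 0.364), 0.02)
  expect_lt(abs(emp[["het"]] - 0.236), 0.02)
  expect_lt(abs(emp[["hom_alt"]] - 0.4), 0.02)
})

test_that("noiseless homozygote melts transition at their amplicon's Tm", {
  tr <- demo_triplet()
  for (g in c("hom_ref", "hom_alt")) {
    curve <- simulate_melt(g, tr, zero_noise(), seed = 2, n_replicates = 1L)
    # steepest descent marks the transition midpoint
    slope <- diff(curve$fluorescence)
    t_inflect <- curve$temperature[which.min(slope)]
    expected <- tr$amplicon_tms[[if (g == "hom_ref") "wild" else "mutant"]]
    expect_lt(abs(t_inflect - expected), 0.11)
  }
})

test_that("a noiseless het melt is the pointwise mean of the homozygote melts", {
  tr <- demo_triplet()
  win <- hrm_windows(tr)
  n <- function(g) normalize_melt(
    simulate_melt(g, tr, zero_noise(), seed = 2, n_replicates = 1L)[, c("temperature", "fluorescence")],
    win$pre, win$post)
  het <- n("het")
  expect_equal(het$normalized,
               (n("hom_ref")$normalized + n("hom_alt")$normalized) / 2,
               tolerance = 1e-3)
})

test_that("replicate wells differ under noise but share the seed deterministically", {
  tr <- demo_triplet()
  a <- simulate_melt("het", tr, curve_noise_model(), seed = 12)
  b <- simulate_melt("het", tr, curve_noise_model(), seed = 12)
  expect_identical(a, b)
  expect_identical(sort(unique(a$replicate)), c(1L, 2L))
  r1 <- a$fluorescence[a$replicate == 1]
  r2 <- a$fluorescence[a$replicate == 2]
  expect_gt(max(abs(r1 - r2)), 0)
})

test_that("amplification reflects allele presence", {
  # het: both reactions cross before cycle 30
  for (ap in c("wild", "mutant")) {
    curve <- simulate_amplification("het", ap, zero_noise(), seed = 14,
                                    n_replicates = 1L)
    cq <- compute_cq(curve[, c("cycle", "fluorescence")], threshold = 50)$cq
    expect_lt(cq, 30)
  }
  # hom_ref with the mutant primer and no nonspecific amplification: flat
  curve <- simulate_amplification("hom_ref", "mutant", zero_noise(), seed = 14,
                                  n_replicates = 1L)
  expect_true(is.na(compute_cq(curve[, c("cycle", "fluorescence")], threshold = 50)$cq))
  # nonspecific late amplification stays beyond the cutoff
  late_noise <- curve_noise_model(nonspecific_prob = 1)
  curve <- simulate_amplification("hom_ref", "mutant", late_noise, seed = 15,
                                  n_replicates = 1L)
  cq <- compute_cq(curve[, c("cycle", "fluorescence")], threshold = 50)$cq
  expect_gt(cq, 30)
})

test_that("experiments emit duplicate wells and a consistent manifest", {
  spec <- cohort_spec(5, 5)
  sim <- simulate_experiment(spec, demo_triplet(), curve_noise_model(), seed = 16)
  # 10 subjects + 3 controls, duplicate wells each
  expect_identical(nrow(sim$manifest), 26L)
  expect_true(all(table(sim$manifest$sample_id) == 2))
  expect_identical(sort(unique(sim$manifest$genotype[sim$manifest$role == "control"])),
                   c("het", "hom_alt", "hom_ref"))
  # every manifest well appears in the melt plate, and qPCR wells split by primer
  expect_true(all(sim$manifest$well %in% sim$melt_plate$well))
  expect_true(all(sim$qpcr_manifest$well %in% sim$qpcr_plate$well))
  expect_identical(nrow(sim$qpcr_manifest), 52L)
})

test_that("simulated cohorts recover their generating odds ratio", {
  spec <- cohort_spec(5000, 5000,
                      c(hom_ref = 20, het = 13, hom_alt = 22) / 55,
                      c(hom_ref = 72, het = 23, hom_alt = 15) / 110)
  cohort <- simulate_cohort(spec, seed = 17)
  tab <- cohort |>
    dplyr::count(.data$group, .data$genotype) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n", values_fill = 0L)
  gt <- genotype_table("rsSIM", tab$genotype, tab$case, tab$control,
                       reference = "hom_ref")
  dom <- association_report(gt)$results
  dom <- dom[dom$model == "dominant", ]
  generating <- (35 / 20) / (38 / 72)
  expect_lt(abs(dom$odds_ratio - generating) / generating, 0.05)
})
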