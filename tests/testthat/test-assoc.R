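# Case-control association statistics on the bundled example counts.

fto <- function() genotype_table("rs9939609", c("TT", "AT", "AA"),
                                 cases = c(20, 13, 22), controls = c(72, 23, 15))

test_that("genotype percentages reproduce the example cohort's printed values", {
  freq <- genotype_frequencies(fto())
  get <- function(g, grp) freq$pct_display[freq$genotype == g & freq$group == grp]
  expect_identical(get("TT", "cases"), 36.4)
  expect_identical(get("AT", "cases"), 23.6)
  expect_identical(get("AA", "cases"), 40)
  expect_identical(get("TT", "controls"), 65.4)  # 65.4545... under display rounding
  expect_identical(get("AT", "controls"), 20.9)
  expect_identical(get("AA", "controls"), 13.6)
})

test_that("degenerate frequency tables behave as documented", {
  mono <- genotype_table("rsM", c("CC", "CT", "TT"), c(55, 0, 0), c(110, 0, 0))
  freq <- genotype_frequencies(mono)
  expect_true(all(freq$pct[freq$genotype == "CC"] == 100))
  empty <- genotype_table("rsE", c("CC", "CT", "TT"), c(0, 0, 0), c(1, 1, 1))
  expect_error(genotype_frequencies(empty), class = "snpmelt_invalid_input")
})

test_that("allele counts follow 2*hom + het", {
  af <- allele_frequencies(fto())
  a_cases <- af[af$allele == "A" & af$group == "cases", ]
  expect_identical(a_cases$count, 2L * 22L + 13L)   # 57 of 110
  expect_equal(a_cases$pct, 100 * 57 / 110)
  t_ctrl <- af[af$allele == "T" & af$group == "controls", ]
  expect_identical(t_ctrl$count, 2L * 72L + 23L)
  # monomorphic: all alt homozygotes
  mono <- genotype_table("rs1800447", c("TT", "CT", "CC"), c(0, 0, 55), c(0, 0, 110))
  af_mono <- allele_frequencies(mono)
  expect_true(all(af_mono$pct[af_mono$allele == "C"] == 100))
  # symmetric: equal homozygote counts, no hets
  sym <- genotype_table("rsS", c("AA", "AG", "GG"), c(10, 0, 10), c(7, 0, 7))
  af_sym <- allele_frequencies(sym)
  expect_true(all(af_sym$pct == 50))
})

test_that("odds ratios and Woolf intervals match the printed example values", {
  aa <- odds_ratio_ci(22, 20, 15, 72)
  expect_equal(round(aa$odds_ratio, 2), 5.28)
  expect_equal(round(aa$ci_low, 3), 2.320)
  expect_equal(round(aa$ci_high, 3), 12.016)
  ct <- odds_ratio_ci(1, 48, 1, 95)
  expect_equal(round(ct$odds_ratio, 3), 1.979)
  expect_equal(round(ct$ci_low, 3), 0.121)
  expect_equal(round(ct$ci_high, 2), 32.33)
  # identity tables
  for (km in list(c(3, 5), c(10, 10), c(7, 2))) {
    expect_equal(odds_ratio_ci(km[1], km[2], km[1], km[2])$odds_ratio, 1)
  }
})

test_that("odds ratio properties: reciprocity, log-symmetry, level monotonicity", {
  withr::with_seed(51, {
    for (i in 1:50) {
      cells <- sample(1:100, 4, replace = TRUE)
      x <- do.call(odds_ratio_ci, as.list(cells))
      y <- do.call(odds_ratio_ci, as.list(cells[c(2, 1, 4, 3)]))
      expect_equal(x$odds_ratio * y$odds_ratio, 1, tolerance = 1e-12)
      expect_equal(log(x$ci_low) + log(x$ci_high), 2 * log(x$odds_ratio),
                   tolerance = 1e-9)
      wider <- do.call(odds_ratio_ci, c(as.list(cells), level = 0.99))
      expect_lt(wider$ci_low, x$ci_low)
      expect_gt(wider$ci_high, x$ci_high)
    }
  })
})

test_that("zero cells take the Haldane-Anscombe correction or error out", {
  z <- odds_ratio_ci(0, 20, 15, 72)
  expect_true(z$corrected)
  expect_equal(z$odds_ratio, (0.5 * 72.5) / (20.5 * 15.5))
  expect_error(odds_ratio_ci(0, 20, 15, 0), class = "snpmelt_undefined_statistic")
})

test_that("Pearson chi-square matches hand evaluation and its symmetries", {
  res <- pearson_chi2(22, 20, 15, 72)
  expect_equal(res$chi2, 17.098639, tolerance = 1e-5)
  expect_equal(res$p_value, 3.548764e-05, tolerance = 1e-4)
  flat <- pearson_chi2(9, 9, 9, 9)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(pearson_chi2(15, 72, 22, 20)$chi2, res$chi2)
  expect_error(pearson_chi2(0, 0, 10, 20), class = "snpmelt_undefined_statistic")
  # agrees with stats::chisq.test without continuity correction
  withr::with_seed(52, {
    for (i in 1:25) {
      cells <- sample(1:60, 4, replace = TRUE)
      m <- matrix(cells, 2, byrow = TRUE)
      expect_equal(pearson_chi2(cells[1], cells[2], cells[3], cells[4])$chi2,
                   unname(chisq.test(m, correct = FALSE)$statistic),
                   tolerance = 1e-9)
    }
  })
})

test_that("dominant collapse pools the non-reference rows", {
  dc <- dominant_collapse(fto())
  expect_identical(nrow(dc), 2L)
  expect_identical(dc$cases, c(20L, 35L))
  expect_identical(dc$controls, c(72L, 38L))
  expect_identical(dc$genotype[2], "AT+AA")
  # zero-het table: pooled row equals the alt homozygotes
  nohet <- genotype_table("rsN", c("CC", "CT", "TT"), c(10, 0, 5), c(20, 0, 3))
  expect_identical(dominant_collapse(nohet)$cases[2], 5L)
})

test_that("the association report carries per-genotype and dominant comparisons", {
  fit <- association_report(fto())
  expect_false(fit$monomorphic)
  expect_identical(nrow(fit$results), 3L)
  expect_equal(round(fit$results$odds_ratio, 3), c(2.035, 5.280, 3.316))
  expect_identical(fit$results$model, c("genotype", "genotype", "dominant"))
  # intervals bracket their estimates
  expect_true(all(fit$results$ci_low <= fit$results$odds_ratio))
  expect_true(all(fit$results$odds_ratio <= fit$results$ci_high))

  fshr <- genotype_table("rs6165", c("GG", "GA", "AA"), c(13, 26, 16), c(29, 53, 28))
  expect_equal(round(association_report(fshr)$results$odds_ratio, 3),
               c(1.094, 1.275, 1.157))
})

test_that("monomorphic loci yield an empty flagged report", {
  mono <- genotype_table("rs1800447", c("TT", "CT", "CC"), c(0, 0, 55), c(0, 0, 110))
  fit <- association_report(mono)
  expect_true(fit$monomorphic)
  expect_identical(nrow(fit$results), 0L)
  expect_error(ggplot2::autoplot(fit), class = "snpmelt_invalid_input")
})

test_that("tidy and glance expose broom-style views of a fit", {
  fit <- association_report(fto())
  td <- generics::tidy(fit)
  expect_identical(names(td)[1:4], c("rsid", "comparison", "model", "estimate"))
  expect_equal(td$estimate, fit$results$odds_ratio)
  gl <- generics::glance(fit)
  expect_identical(gl$n_cases, 55L)
  expect_identical(gl$n_controls, 110L)
  expect_identical(gl$n_comparisons, 3L)
})

test_that("multi-locus counts run end to end, flagging monomorphic loci", {
  counts <- pcos_genotype_counts()
  res <- associate_all(counts)
  expect_identical(sum(res$model == "monomorphic"), 2L)  # both LHB loci
  fto_dom <- res[res$rsid == "rs9939609" & res$model == "dominant", ]
  expect_equal(round(fto_dom$odds_ratio, 3), 3.316)
  gnrh <- res[res$rsid == "rs6185" & !is.na(res$comparison), ]
  expect_identical(nrow(gnrh), 1L)   # CC unobserved; only GC vs GG, no dominant row
  expect_equal(round(gnrh$odds_ratio, 3), 0.686)
})
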