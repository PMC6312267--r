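# Three-primer design rules, routing, and compliance checking.

test_that("a designed triplet obeys the stated allele-specific primer rules", {
  tg <- demo_target()
  tr <- demo_triplet()
  st <- snpmelt:::design_strand(tg, tr$orientation)

  # 3' terminal bases carry the alleles on the design strand
  expect_identical(substr(tr$wild_primer, nchar(tr$wild_primer), nchar(tr$wild_primer)),
                   st$ref)
  expect_identical(substr(tr$mutant_primer, nchar(tr$mutant_primer), nchar(tr$mutant_primer)),
                   st$alt)

  # exactly one deliberate penultimate mismatch, shared by both primers
  pen_w <- substr(tr$wild_primer, nchar(tr$wild_primer) - 1L, nchar(tr$wild_primer) - 1L)
  pen_m <- substr(tr$mutant_primer, nchar(tr$mutant_primer) - 1L, nchar(tr$mutant_primer) - 1L)
  t_pen <- substr(st$tmpl, st$pos - 1L, st$pos - 1L)
  expect_identical(pen_w, pen_m)
  expect_false(pen_w == t_pen)

  # one primer gets G/C (raising) mutations, the other A/T (lowering)
  roles <- sort(unname(tr$roles))
  expect_identical(roles, c("lowering", "raising"))
  raising <- if (tr$roles[["wild"]] == "raising") tr$introduced_mutations_wild
             else tr$introduced_mutations_mut
  lowering <- if (tr$roles[["wild"]] == "lowering") tr$introduced_mutations_wild
              else tr$introduced_mutations_mut
  expect_true(all(raising$to %in% c("G", "C")))
  expect_true(all(lowering$to %in% c("A", "T")))

  # mutations confined to the 5' half
  expect_true(all(tr$introduced_mutations_wild$primer_pos <= floor(nchar(tr$wild_primer) / 2)))
  expect_true(all(tr$introduced_mutations_mut$primer_pos <= floor(nchar(tr$mutant_primer) / 2)))

  # amplicon separation at least the configured minimum, opposite shifts
  expect_gte(tr$separation, tr$config$min_separation)
  expect_true(all(check_triplet(tr, tg)$pass))
})

test_that("design is deterministic", {
  tg <- make_target(77)
  a <- design_triplet(tg)
  b <- design_triplet(tg)
  expect_identical(a, b)
})

test_that("every successful design on random targets passes all rule checks", {
  withr::with_seed(21, {
    designed <- 0L
    for (i in 1:30) {
      alleles <- sample(c("A", "C", "G", "T"), 2)
      tg <- snp_target(paste0("rs", i), random_dna(120, gc = 0.5),
                       random_dna(120, gc = 0.5), alleles[1], alleles[2])
      tr <- tryCatch(design_triplet(tg), error = function(e) NULL)
      if (is.null(tr)) next
      designed <- designed + 1L
      chk <- check_triplet(tr, tg)
      expect_true(all(chk$pass),
                  info = paste("violations:", paste(chk$check[!chk$pass], collapse = ",")))
    }
    expect_gt(designed, 10L)
  })
})

test_that("infeasible separation raises a design failure naming the constraint", {
  tg <- demo_target()
  expect_error(design_triplet(tg, design_config(min_separation = 30)),
               regexp = "separation", class = "snpmelt_design_failure")
})

test_that("SNP targets validate their inputs", {
  expect_error(snp_target("rs1", "ACGT", "ACGT", "C", "C"),
               class = "snpmelt_invalid_input")
  expect_error(snp_target("rs1", "ACGT", "ACGT", "X", "T"),
               class = "snpmelt_invalid_input")
  expect_error(snp_target("rs1", "ACGNACGT", "ACGTACGT", "C", "T"),
               class = "snpmelt_invalid_input")
  # N far from the SNP is tolerated
  tg <- snp_target("rs1", paste0("N", random_dna(60)), random_dna(60), "C", "T")
  expect_s3_class(tg, "snp_target")
})

test_that("assays route to HRM within the 58-60 window and AS-qPCR above it", {
  expect_identical(route_method(c(58.5, 59.2, 59.9)), "HRM")
  expect_identical(route_method(c(59.0, 63.0)), "AS-qPCR")
  # the 60.0 boundary belongs to HRM (closed interval)
  expect_identical(route_method(c(58.2, 60.0)), "HRM")
  expect_error(route_method(c(55.0, 57.9)), class = "snpmelt_unroutable")
})

test_that("published allele-specific primer pairs pass the structural checks", {
  pp <- published_primers()
  for (r in c("rs9939609", "rs2293275")) {
    row <- pp[pp$rsid == r, ]
    chk <- check_primer_pair(row$wild_primer, row$mutant_primer,
                             row$wild_allele, row$mut_allele)
    expect_true(all(chk$pass), info = r)
  }
  # the LHCGR mutant primer's extra mutations sit in its 5' region
  lh <- pp[pp$rsid == "rs2293275", ]
  chk <- check_primer_pair(lh$wild_primer, lh$mutant_primer, "T", "C")
  expect_match(chk$detail[chk$check == "mutations_in_5p_half"], "matched 3' block 2[0-9] nt")
})

test_that("check_triplet reports constructed violations without failing others", {
  tg <- demo_target()
  tr <- demo_triplet()
  broken <- tr
  # remove the penultimate mismatch: restore the template base
  st <- snpmelt:::design_strand(tg, tr$orientation)
  t_pen <- substr(st$tmpl, st$pos - 1L, st$pos - 1L)
  lw <- nchar(broken$wild_primer)
  lm <- nchar(broken$mutant_primer)
  broken$wild_primer <- snpmelt:::apply_subs(broken$wild_primer, lw - 1L, t_pen)
  broken$mutant_primer <- snpmelt:::apply_subs(broken$mutant_primer, lm - 1L, t_pen)
  chk <- check_triplet(broken, tg)
  expect_false(chk$pass[chk$check == "penultimate_mismatch"])
  expect_true(chk$pass[chk$check == "wild_3p_allele"])
  expect_true(chk$pass[chk$check == "common_primer_unmodified"])
})

test_that("triplet export lists primers 5'->3' in grouped-triplet order", {
  tab <- triplets_to_tibble(demo_triplet())
  expect_identical(tab$role, c("wild", "mutant", "common"))
  expect_identical(nrow(tab), 3L)
  expect_true(all(grepl("^[ACGT]+$", tab$sequence)))
})
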