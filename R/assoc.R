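# Case-control association statistics.
#
# Genotype counts per group are compared against the reference (wild-type)
# genotype with Pearson chi-square tests and odds ratios carrying Woolf
# log-normal confidence intervals, plus a dominant-model comparison that
# pools carriers of the variant allele. Percentages, ORs and CI bounds are
# computed at full precision and rounded only for display.

#' Build a genotype count table
#'
#' @param rsid Locus identifier.
#' @param genotypes Character vector of genotype labels (e.g. `c("TT", "AT",
#'   "AA")`), reference first by convention but any order is accepted.
#' @param cases,controls Non-negative integer counts per genotype.
#' @param reference The reference (wild-type) genotype label.
#' @return A tibble of class `genotype_table` with columns `rsid`,
#'   `genotype`, `cases`, `controls`, `reference` (logical).
#' @export
genotype_table <- function(rsid, genotypes, cases, controls, reference = genotypes[1]) {
  stopifnot(length(genotypes) == length(cases), length(cases) == length(controls))
  cases <- as.integer(cases); controls <- as.integer(controls)
  if (any(cases < 0) || any(controls < 0)) {
    snpmelt_abort("genotype counts must be non-negative", "invalid_input")
  }
  if (!reference %in% genotypes) {
    snpmelt_abort("reference genotype not among the genotype labels", "invalid_input")
  }
  out <- tibble::tibble(rsid = rsid, genotype = genotypes,
                        cases = cases, controls = controls,
                        reference = genotypes == reference)
  class(out) <- c("genotype_table", class(out))
  out
}

assert_genotype_table <- function(table) {
  if (!all(c("rsid", "genotype", "cases", "controls", "reference") %in% names(table))) {
    snpmelt_abort("not a genotype table (need rsid, genotype, cases, controls, reference)",
                  "invalid_input")
  }
  invisible(table)
}

#' Genotype frequencies per group
#'
#' Percentages of each genotype within cases and within controls. `pct` is
#' the full-precision percentage; `pct_display` is rounded to one decimal for
#' presentation (two-stage: to two decimals, then half-to-even to one, the
#' convention used by the bundled example tables).
#'
#' @param table A [genotype_table()].
#' @return Long tibble: `rsid`, `genotype`, `group`, `count`, `pct`,
#'   `pct_display`.
#' @export
genotype_frequencies <- function(table) {
  assert_genotype_table(table)
  if (sum(table$cases) == 0L || sum(table$controls) == 0L) {
    snpmelt_abort("both groups must contain at least one subject", "invalid_input")
  }
  table |>
    tidyr::pivot_longer(c("cases", "controls"), names_to = "group", values_to = "count") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = 100 * .data$count / sum(.data$count),
                  pct_display = round_pct_display(.data$pct)) |>
    dplyr::ungroup() |>
    dplyr::select("rsid", "genotype", "group", "count", "pct", "pct_display")
}

parse_genotype_alleles <- function(labels) {
  if (any(nchar(labels) != 2L)) {
    snpmelt_abort("genotype labels must be two allele characters (e.g. 'AT')",
                  "invalid_input")
  }
  alleles <- sort(unique(unlist(strsplit(labels, ""))))
  if (length(alleles) > 2L) {
    snpmelt_abort("genotype labels imply more than two alleles; locus is not biallelic",
                  "invalid_input")
  }
  alleles
}

#' Allele counts and frequencies per group
#'
#' Each homozygote contributes two copies of its allele and each heterozygote
#' one of each, so allele totals are `2n` per group.
#'
#' @param table A [genotype_table()] with two-character genotype labels.
#' @return Tibble: `rsid`, `allele`, `group`, `count`, `pct`, `pct_display`.
#' @export
allele_frequencies <- function(table) {
  assert_genotype_table(table)
  alleles <- parse_genotype_alleles(table$genotype)
  long <- tidyr::pivot_longer(table, c("cases", "controls"),
                              names_to = "group", values_to = "count")
  purrr::map_dfr(alleles, function(al) {
    long |>
      dplyr::mutate(copies = stringr::str_count(.data$genotype, stringr::fixed(al))) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(total = 2L * sum(.data$count),
                       count = sum(.data$copies * .data$count), .groups = "drop") |>
      dplyr::transmute(rsid = table$rsid[1], allele = al, group = .data$group,
                       count = .data$count,
                       pct = 100 * .data$count / .data$total,
                       pct_display = round_pct_display(.data$pct))
  })
}

#' Odds ratio with a Woolf confidence interval
#'
#' `OR = (a d)/(b c)` for a 2x2 table with `a` = exposed cases, `b` =
#' reference cases, `c` = exposed controls, `d` = reference controls. The
#' confidence interval is Woolf's log-normal interval,
#' `exp(ln OR +- z sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells (flagged in the
#' output); if both cells of a diagonal are zero even after correction the OR
#' is undefined and an error is raised.
#'
#' @param a,b,c,d Non-negative counts.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `level`, `corrected`.
#' @examples
#' odds_ratio_ci(22, 20, 15, 72)
#' @export
odds_ratio_ci <- function(a, b, c, d, level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) {
    snpmelt_abort("cell counts must be non-negative", "invalid_input")
  }
  if ((a + d) == 0 || (b + c) == 0) {
    snpmelt_abort("both cells of a diagonal are zero; odds ratio undefined",
                  "undefined_statistic")
  }
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(a = a, b = b, c = c, d = d,
                 odds_ratio = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 level = level, corrected = corrected)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form without continuity correction:
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, compared against the
#' chi-square distribution with 1 degree of freedom.
#'
#' @inheritParams odds_ratio_ci
#' @return One-row tibble: `chi2`, `p_value`, `df`.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) {
    snpmelt_abort("cell counts must be non-negative", "invalid_input")
  }
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    snpmelt_abort("a zero marginal makes the chi-square statistic undefined",
                  "undefined_statistic")
  }
  n <- sum(counts)
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  tibble::tibble(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 df = 1L)
}

#' Collapse a genotype table to the dominant model
#'
#' Pools the heterozygote and variant-homozygote rows (all non-reference
#' genotypes) into a single carrier row, leaving the reference genotype
#' untouched.
#'
#' @param table A [genotype_table()] with at least the reference and one
#'   non-reference genotype row.
#' @return A two-row `genotype_table` (reference row, pooled carrier row).
#' @export
dominant_collapse <- function(table) {
  assert_genotype_table(table)
  if (sum(!table$reference) < 1L || sum(table$reference) != 1L) {
    snpmelt_abort("dominant collapse needs one reference row and at least one other row",
                  "invalid_input")
  }
  ref <- table[table$reference, ]
  rest <- table[!table$reference, ]
  pooled <- tibble::tibble(
    rsid = ref$rsid, genotype = paste(rest$genotype, collapse = "+"),
    cases = sum(rest$cases), controls = sum(rest$controls), reference = FALSE
  )
  out <- dplyr::bind_rows(ref, pooled)
  class(out) <- c("genotype_table", class(tibble::tibble()))
  out
}

#' Case-control association report for one locus
#'
#' One comparison per non-reference genotype against the reference genotype,
#' plus the dominant-model comparison (all carriers vs reference), each with
#' the odds ratio, Woolf confidence interval, and uncorrected Pearson
#' chi-square p-value. Monomorphic tables (all subjects one genotype) yield
#' an empty result flagged `monomorphic`. Non-reference genotypes observed in
#' neither group are skipped.
#'
#' @param table A [genotype_table()].
#' @param level Confidence level for the intervals.
#' @return An object of class `snp_assoc`: list with `table`, `results` (a
#'   tibble with one row per comparison) and `monomorphic`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' tab <- genotype_table("rs9939609", c("TT", "AT", "AA"),
#'                       cases = c(20, 13, 22), controls = c(72, 23, 15))
#' association_report(tab)
#' @export
association_report <- function(table, level = 0.95) {
  assert_genotype_table(table)
  present <- table$cases + table$controls > 0L
  monomorphic <- sum(present) < 2L
  ref <- table[table$reference, ]
  if (nrow(ref) != 1L) {
    snpmelt_abort("table must flag exactly one reference genotype", "invalid_input")
  }

  results <- tibble::tibble()
  if (!monomorphic && present[table$reference]) {
    rows <- table[!table$reference & present, ]
    compare <- function(label, exp_cases, exp_controls) {
      orci <- odds_ratio_ci(exp_cases, ref$cases, exp_controls, ref$controls, level)
      chi <- pearson_chi2(exp_cases, ref$cases, exp_controls, ref$controls)
      dplyr::bind_cols(
        tibble::tibble(rsid = ref$rsid, comparison = paste0(label, " vs ", ref$genotype),
                       model = if (grepl("+", label, fixed = TRUE)) "dominant" else "genotype"),
        orci, chi)
    }
    per_genotype <- purrr::pmap_dfr(
      list(rows$genotype, rows$cases, rows$controls), compare)
    dominant <- if (nrow(rows) > 1L) {
      compare(paste(rows$genotype, collapse = "+"), sum(rows$cases), sum(rows$controls))
    } else tibble::tibble()
    results <- dplyr::bind_rows(per_genotype, dominant)
  }

  structure(list(table = table, results = results,
                 monomorphic = monomorphic, level = level),
            class = "snp_assoc")
}

#' @export
print.snp_assoc <- function(x, ...) {
  cat(sprintf("<snp_assoc> %s  (%d cases, %d controls)\n",
              x$table$rsid[1], sum(x$table$cases), sum(x$table$controls)))
  if (x$monomorphic) {
    cat("  monomorphic locus: no comparison possible\n")
  } else {
    df <- x$results
    cat(sprintf("  %-14s OR %6s  (%s%% CI %s - %s)  p %s\n",
                df$comparison, format_or(df$odds_ratio), format(100 * x$level),
                format_or(df$ci_low), format_or(df$ci_high),
                signif(df$p_value, 2)), sep = "")
  }
  invisible(x)
}

# Display formatting used in reports: three decimals, trimmed.
format_or <- function(x) formatC(round(x, 3), format = "fg", digits = 7)

#' Association reports for a multi-locus counts table
#'
#' Runs [association_report()] per locus of a long counts tibble (the format
#' of [read_counts_tsv()]) and binds the per-comparison rows.
#'
#' @param counts Tibble with columns `rsid`, `genotype`, `cases`, `controls`,
#'   `reference` (logical), optionally `gene`.
#' @param level Confidence level.
#' @return Tibble of comparisons across loci; monomorphic loci contribute a
#'   single row with `model = "monomorphic"` and `NA` statistics.
#' @export
associate_all <- function(counts, level = 0.95) {
  assert_genotype_table(counts)
  purrr::map_dfr(split(counts, factor(counts$rsid, levels = unique(counts$rsid))),
                 function(tab) {
    class(tab) <- c("genotype_table", class(tibble::tibble()))
    fit <- association_report(tab, level)
    if (fit$monomorphic) {
      tibble::tibble(rsid = tab$rsid[1], comparison = NA_character_,
                     model = "monomorphic")
    } else fit$results
  })
}
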