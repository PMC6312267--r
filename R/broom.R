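# broom-style accessors for association fits.

#' Tidy an association fit
#'
#' One row per comparison with estimate, interval, and test columns in broom
#' naming (`estimate` is the odds ratio).
#'
#' @param x An `snp_assoc` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy snp_assoc
#' @export
tidy.snp_assoc <- function(x, ...) {
  if (x$monomorphic || nrow(x$results) == 0L) {
    return(tibble::tibble(rsid = x$table$rsid[1], comparison = character(0)))
  }
  x$results |>
    dplyr::transmute(
      rsid = .data$rsid, comparison = .data$comparison, model = .data$model,
      estimate = .data$odds_ratio,
      conf.low = .data$ci_low, conf.high = .data$ci_high,
      statistic = .data$chi2, p.value = .data$p_value,
      a = .data$a, b = .data$b, c = .data$c, d = .data$d
    )
}

#' One-row summary of an association fit
#'
#' @param x An `snp_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble: cohort sizes, number of comparisons, smallest
#'   p-value, monomorphic flag.
#' @method glance snp_assoc
#' @export
glance.snp_assoc <- function(x, ...) {
  tibble::tibble(
    rsid = x$table$rsid[1],
    n_cases = sum(x$table$cases),
    n_controls = sum(x$table$controls),
    n_comparisons = nrow(x$results),
    min_p = if (nrow(x$results)) min(x$results$p_value) else NA_real_,
    monomorphic = x$monomorphic
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
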