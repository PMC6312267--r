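# Shared internal helpers: DNA string utilities and classed error conditions.

.BASES <- c("A", "C", "G", "T")

snpmelt_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(paste0("snpmelt_", class), "snpmelt_error"), ...)
}

check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  if (!rlang::is_string(x) || nchar(x) == 0L) {
    snpmelt_abort(paste0(what, " must be a non-empty string"), "invalid_input")
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x)) {
    snpmelt_abort(
      sprintf("%s contains characters outside {%s}", what,
              paste(strsplit(alphabet, "")[[1]], collapse = ",")),
      "invalid_input"
    )
  }
  invisible(x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences (`A`, `C`, `G`, `T`, optionally
#'   `N`), written 5'->3'. The result is the complementary strand, also 5'->3'.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", toupper(s))
    paste(rev(seq_chars(comp)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' GC fraction of a DNA sequence
#'
#' @param x DNA string.
#' @return Fraction of bases that are G or C, in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  ch <- seq_chars(toupper(x))
  mean(ch %in% c("G", "C"))
}

is_strong <- function(base) base %in% c("G", "C")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Display rounding for percentages: round to 2 decimals first, then to 1
# decimal with ties going to the even digit. Integer arithmetic throughout so
# binary floating point cannot flip a boundary case.
round_pct_display <- function(p) {
  vapply(p, function(x) {
    v <- round(x * 100)            # value in hundredths of a percent
    q <- v %/% 10L
    r <- v %% 10L
    d <- if (r > 5L) q + 1L else if (r < 5L) q else if (q %% 2L == 0L) q else q + 1L
    d / 10
  }, numeric(1))
}

new_well_ids <- function(n) {
  rows <- LETTERS[1:8]
  cols <- sprintf("%02d", 1:12)
  plate <- as.vector(outer(rows, cols, paste0))
  k <- ceiling(n / length(plate))
  ids <- paste0(rep(seq_len(k), each = length(plate)), "_", rep(plate, k))
  ids[seq_len(n)]
}
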