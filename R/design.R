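# Three-primer assay design (modified CADMA).
#
# For a biallelic SNP, two allele-specific primers anchor their 3'-terminal
# base on the SNP (one per allele) and a shared common primer closes the
# amplicon. Each allele-specific primer carries (i) a deliberate mismatch at
# the second base from its 3' end, sharpening allelic discrimination, and
# (ii) one or more mutations in its 5' half that are copied into the product:
# G/C mutations raise the Tm of one allele's amplicon, A/T mutations lower the
# other's, so the two products melt apart and a single-tube melt curve (or a
# pair of allele-specific qPCR reactions) reads out the genotype.

#' Design configuration
#'
#' Tunable constraints for [design_triplet()]. Defaults: primer length 18-30
#' nt, amplicon 60-200 bp, matched primer Tm within 58-66 degrees C, at least
#' 1.5 degrees C predicted separation between the two allele amplicons, and at
#' most 4 Tm-shifting mutations per allele-specific primer.
#'
#' @param primer_len Length range (min, max) for all primers, nt.
#' @param amplicon_len Allowed amplicon length range, bp.
#' @param primer_tm_range Acceptable matched primer Tm window, degrees C.
#' @param hrm_tm_range Primer-Tm window routed to HRM; above its upper bound
#'   the assay is routed to AS-qPCR (see [route_method()]).
#' @param min_separation Minimum |Tm difference| between allele amplicons.
#' @param max_introduced Maximum Tm-shifting mutations per allele primer.
#' @param monovalent,oligo_conc Salt (M) and oligo concentration (M) used for
#'   all Tm predictions.
#' @param min_gap Minimum distance (nt) between the SNP and the common
#'   primer's near end.
#' @return A named list of constraints.
#' @export
design_config <- function(primer_len = c(18L, 30L),
                          amplicon_len = c(60L, 200L),
                          primer_tm_range = c(58, 66),
                          hrm_tm_range = c(58, 60),
                          min_separation = 1.5,
                          max_introduced = 4L,
                          monovalent = 0.05,
                          oligo_conc = 2e-7,
                          min_gap = 30L) {
  cfg <- list(primer_len = as.integer(primer_len), amplicon_len = as.integer(amplicon_len),
              primer_tm_range = primer_tm_range, hrm_tm_range = hrm_tm_range,
              min_separation = min_separation, max_introduced = as.integer(max_introduced),
              monovalent = monovalent, oligo_conc = oligo_conc, min_gap = as.integer(min_gap))
  stopifnot(cfg$primer_len[1] >= 10L, cfg$primer_len[2] >= cfg$primer_len[1],
            cfg$min_separation > 0, cfg$max_introduced >= 1L)
  cfg
}

#' Construct a SNP target
#'
#' A biallelic locus with its flanking genomic sequence. The assembled target
#' sequence is `flank_5p + ref_allele + flank_3p`; the SNP sits at position
#' `nchar(flank_5p) + 1` (1-based).
#'
#' @param rsid Locus identifier (e.g. an rsID).
#' @param flank_5p,flank_3p Flanking sequences, 5'->3' on the same strand.
#'   At least 60 nt each is recommended; `N` is tolerated only further than
#'   40 nt from the SNP.
#' @param ref_allele,alt_allele Single bases in `{A,C,G,T}`, distinct.
#' @return An object of class `snp_target`.
#' @export
snp_target <- function(rsid, flank_5p, flank_3p, ref_allele, alt_allele) {
  stopifnot(rlang::is_string(rsid))
  check_dna(flank_5p, "flank_5p", allow_n = TRUE)
  check_dna(flank_3p, "flank_3p", allow_n = TRUE)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (!ref_allele %in% .BASES || !alt_allele %in% .BASES) {
    snpmelt_abort("alleles must be single bases in {A,C,G,T}", "invalid_input")
  }
  if (ref_allele == alt_allele) {
    snpmelt_abort("ref and alt alleles must differ", "invalid_input")
  }
  near5 <- substr(flank_5p, max(1L, nchar(flank_5p) - 39L), nchar(flank_5p))
  near3 <- substr(flank_3p, 1L, min(40L, nchar(flank_3p)))
  if (grepl("N", paste0(near5, near3), fixed = TRUE)) {
    snpmelt_abort("flanks contain N within 40 bases of the SNP", "invalid_input")
  }
  structure(
    list(rsid = rsid, flank_5p = toupper(flank_5p), flank_3p = toupper(flank_3p),
         ref_allele = ref_allele, alt_allele = alt_allele,
         sequence = paste0(toupper(flank_5p), ref_allele, toupper(flank_3p)),
         snp_position = nchar(flank_5p) + 1L),
    class = "snp_target"
  )
}

#' @export
print.snp_target <- function(x, ...) {
  cat(sprintf("<snp_target> %s  %s/%s at position %d of %d nt\n",
              x$rsid, x$ref_allele, x$alt_allele, x$snp_position, nchar(x$sequence)))
  invisible(x)
}

# The template strand the primers are written against, for a given
# orientation: "forward" designs the allele primers on the given strand,
# "reverse" on its reverse complement (alleles complemented accordingly).
design_strand <- function(target, orientation) {
  if (orientation == "forward") {
    list(tmpl = target$sequence, pos = target$snp_position,
         ref = target$ref_allele, alt = target$alt_allele)
  } else {
    n <- nchar(target$sequence)
    list(tmpl = revcomp(target$sequence), pos = n - target$snp_position + 1L,
         ref = complement_base(target$ref_allele),
         alt = complement_base(target$alt_allele))
  }
}

transversions <- function(base) {
  switch(base, A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"),
         snpmelt_abort(sprintf("no transversion for base '%s'", base), "invalid_input"))
}

gc_clamp_run <- function(primer) {
  ch <- rev(seq_chars(primer))
  run <- 0L
  for (b in ch) {
    if (is_strong(b)) run <- run + 1L else break
  }
  run
}

# Pick the penultimate-mismatch base: a transversion of the template base just
# 5' of the SNP, preferring one that keeps the 3' G/C clamp at 3 or shorter
# for both allele primers.
choose_penultimate <- function(tmpl, pos, ref, alt) {
  t_pen <- substr(tmpl, pos - 1L, pos - 1L)
  cands <- transversions(t_pen)
  tail3 <- substr(tmpl, max(1L, pos - 5L), pos - 2L)
  for (cand in cands) {
    clamps <- vapply(c(ref, alt), function(allele)
      gc_clamp_run(paste0(tail3, cand, allele)), integer(1))
    if (all(clamps <= 3L)) return(list(base = cand, template_base = t_pen))
  }
  list(base = cands[1L], template_base = t_pen)
}

apply_subs <- function(s, positions, bases) {
  ch <- seq_chars(s)
  ch[positions] <- bases
  paste(ch, collapse = "")
}

# Build one allele-specific primer: 3' end anchored on the SNP, penultimate
# mismatch substituted, k Tm-shifting mutations in the 5' half (nearest-to-5'
# first), and the shortest length whose matched Tm falls in the window.
build_as_primer <- function(tmpl, pos, allele, pen_base, role, k, cfg) {
  for (L in seq(cfg$primer_len[1], cfg$primer_len[2])) {
    start <- pos - L + 1L
    if (start < 1L) return(NULL)
    region <- substr(tmpl, start, pos)
    if (grepl("N", region, fixed = TRUE)) next
    base_primer <- apply_subs(region, c(L - 1L, L), c(pen_base, allele))
    half <- floor(L / 2)
    ch <- seq_chars(base_primer)
    idx <- seq_len(half)
    sub_from <- if (role == "raising") c("A", "T") else c("G", "C")
    sub_map <- c(A = "G", T = "C", G = "A", C = "T")
    eligible <- idx[ch[idx] %in% sub_from]
    if (length(eligible) < k) next
    chosen <- eligible[seq_len(k)]
    primer <- apply_subs(base_primer, chosen, unname(sub_map[ch[chosen]]))
    tm <- primer_tm(oligo_duplex(primer, concentration = cfg$oligo_conc,
                                 monovalent = cfg$monovalent))
    if (tm >= cfg$primer_tm_range[1] && tm <= cfg$primer_tm_range[2]) {
      return(list(
        sequence = primer, length = L, start = start, tm = tm, role = role,
        introduced = tibble::tibble(
          primer_pos = chosen,
          from = ch[chosen],
          to = unname(sub_map[ch[chosen]])
        )
      ))
    }
  }
  NULL
}

choose_common_primer <- function(tmpl, pos, cfg) {
  n <- nchar(tmpl)
  e_min <- pos + cfg$min_gap + cfg$primer_len[1]
  e_max <- min(n, pos + cfg$amplicon_len[2] - cfg$primer_len[1])
  if (e_min > e_max) return(NULL)
  for (e in seq(e_min, e_max)) {
    for (Lc in seq(cfg$primer_len[1], cfg$primer_len[2])) {
      start <- e - Lc + 1L
      if (start <= pos + 5L) break
      region <- substr(tmpl, start, e)
      if (grepl("N", region, fixed = TRUE)) next
      primer <- revcomp(region)
      tm <- primer_tm(oligo_duplex(primer, concentration = cfg$oligo_conc,
                                   monovalent = cfg$monovalent))
      if (tm >= cfg$primer_tm_range[1] && tm <= cfg$primer_tm_range[2]) {
        return(list(sequence = primer, length = Lc, start = start, end = e, tm = tm))
      }
    }
  }
  NULL
}

allele_amplicon <- function(tmpl, primer, pos, allele, pen_base, amp_end) {
  abs_pos <- primer$start + primer$introduced$primer_pos - 1L
  s <- substr(tmpl, primer$start, amp_end)
  rel <- function(p) p - primer$start + 1L
  s <- apply_subs(s, c(rel(abs_pos), rel(pos - 1L), rel(pos)),
                  c(primer$introduced$to, pen_base, allele))
  s
}

#' Design a three-primer genotyping set for a SNP
#'
#' Searches deterministically for a wild-type-specific, mutant-specific and
#' common primer satisfying the modified-CADMA rules: allele primers anchor
#' their 3' end on the SNP base; each carries exactly one deliberate mismatch
#' at the second base from its 3' end; Tm-raising (G/C) mutations are
#' introduced into the allele-specific primer whose unmodified amplicon melts
#' lower, Tm-lowering (A/T) mutations into the other, confined to the 5' half
#' of the primer, escalating from 1 mutation per primer until the predicted
#' amplicon Tm separation reaches `constraints$min_separation`; the common
#' primer is unmodified template. The forward orientation is tried first, then
#' the reverse; the search order is fixed, so the same target and constraints
#' always give a byte-identical design.
#'
#' @param target An [snp_target()].
#' @param constraints A [design_config()].
#' @return A `primer_triplet` object: primer sequences (5'->3'), introduced
#'   mutations, predicted primer and amplicon Tms, amplicon sequences, Tm
#'   separation, detection `method` ("HRM" or "AS-qPCR") and annealing
#'   temperature.
#' @seealso [check_triplet()], [route_method()]
#' @export
design_triplet <- function(target, constraints = design_config()) {
  stopifnot(inherits(target, "snp_target"))
  cfg <- constraints
  failures <- character()

  for (orientation in c("forward", "reverse")) {
    st <- design_strand(target, orientation)
    tmpl <- st$tmpl; pos <- st$pos

    if (substr(tmpl, pos, pos) != st$ref) {
      snpmelt_abort("SNP base inconsistent with flanking sequence", "invalid_input")
    }
    pen <- choose_penultimate(tmpl, pos, st$ref, st$alt)
    common <- choose_common_primer(tmpl, pos, cfg)
    if (is.null(common)) {
      failures <- c(failures, sprintf("%s: no common primer in Tm window", orientation))
      next
    }

    # raising mutations go to the allele whose unmodified amplicon melts lower
    raising_allele <-
      if (is_strong(st$ref) == is_strong(st$alt)) "ref"
      else if (is_strong(st$ref)) "alt" else "ref"

    found <- NULL
    for (k in seq_len(cfg$max_introduced)) {
      wildP <- build_as_primer(tmpl, pos, st$ref, pen$base,
                               if (raising_allele == "ref") "raising" else "lowering", k, cfg)
      mutP <- build_as_primer(tmpl, pos, st$alt, pen$base,
                              if (raising_allele == "alt") "raising" else "lowering", k, cfg)
      if (is.null(wildP) || is.null(mutP)) next
      amp_len_w <- common$end - wildP$start + 1L
      amp_len_m <- common$end - mutP$start + 1L
      if (max(amp_len_w, amp_len_m) > cfg$amplicon_len[2] ||
          min(amp_len_w, amp_len_m) < cfg$amplicon_len[1]) next
      amp_w <- allele_amplicon(tmpl, wildP, pos, st$ref, pen$base, common$end)
      amp_m <- allele_amplicon(tmpl, mutP, pos, st$alt, pen$base, common$end)
      tm_w <- amplicon_tm(amp_w, cfg$monovalent)
      tm_m <- amplicon_tm(amp_m, cfg$monovalent)
      if (abs(tm_w - tm_m) >= cfg$min_separation) {
        found <- list(wildP = wildP, mutP = mutP, amp_w = amp_w, amp_m = amp_m,
                      tm_w = tm_w, tm_m = tm_m, k = k)
        break
      }
    }
    if (is.null(found)) {
      failures <- c(failures, sprintf("%s: amplicon Tm separation < %.2f",
                                      orientation, cfg$min_separation))
      next
    }

    tms <- c(wild = found$wildP$tm, mutant = found$mutP$tm, common = common$tm)
    triplet <- structure(
      list(
        rsid = target$rsid,
        orientation = orientation,
        wild_primer = found$wildP$sequence,
        mutant_primer = found$mutP$sequence,
        common_primer = common$sequence,
        ref_allele = st$ref, alt_allele = st$alt,
        penultimate = list(primer_base = pen$base, template_base = pen$template_base),
        introduced_mutations_wild = found$wildP$introduced,
        introduced_mutations_mut = found$mutP$introduced,
        roles = c(wild = found$wildP$role, mutant = found$mutP$role),
        primer_tms = tms,
        amplicon_tms = c(wild = found$tm_w, mutant = found$tm_m),
        amplicon_seqs = c(wild = found$amp_w, mutant = found$amp_m),
        separation = round(abs(found$tm_w - found$tm_m), 2),
        annealing_temp = round(min(tms)),
        coords = list(snp_pos = pos, wild_start = found$wildP$start,
                      mut_start = found$mutP$start,
                      common_start = common$start, amplicon_end = common$end),
        config = cfg
      ),
      class = "primer_triplet"
    )
    triplet$method <- route_method(triplet)
    return(triplet)
  }

  snpmelt_abort(
    paste0("no feasible primer triplet: ", paste(failures, collapse = "; ")),
    "design_failure"
  )
}

#' @export
print.primer_triplet <- function(x, ...) {
  cat(sprintf("<primer_triplet> %s (%s strand, method %s)\n",
              x$rsid, x$orientation, x$method))
  cat(sprintf("  wild   (%s) %s  Tm %.2f\n", x$ref_allele, x$wild_primer, x$primer_tms[["wild"]]))
  cat(sprintf("  mutant (%s) %s  Tm %.2f\n", x$alt_allele, x$mutant_primer, x$primer_tms[["mutant"]]))
  cat(sprintf("  common     %s  Tm %.2f\n", x$common_primer, x$primer_tms[["common"]]))
  cat(sprintf("  amplicon Tms %.2f / %.2f (separation %.2f), annealing %d C\n",
              x$amplicon_tms[["wild"]], x$amplicon_tms[["mutant"]], x$separation,
              x$annealing_temp))
  invisible(x)
}

#' Route an assay to HRM or AS-qPCR by primer Tm
#'
#' Assays whose hottest allele-specific primer melts within the HRM window
#' (default 58-60 degrees C, boundaries included) are read by high-resolution
#' melting in a single tube; hotter primers are read by two allele-specific
#' qPCR reactions. Below the window no routing rule exists and an error is
#' raised.
#'
#' @param triplet A `primer_triplet`, or a numeric vector of allele-specific
#'   primer Tms.
#' @param hrm_tm_range HRM routing window (closed interval), degrees C.
#' @return `"HRM"` or `"AS-qPCR"`.
#' @export
route_method <- function(triplet, hrm_tm_range = c(58, 60)) {
  tms <- if (inherits(triplet, "primer_triplet")) {
    if (!is.null(triplet$config$hrm_tm_range)) hrm_tm_range <- triplet$config$hrm_tm_range
    triplet$primer_tms[c("wild", "mutant")]
  } else as.numeric(triplet)
  if (!length(tms) || anyNA(tms)) {
    snpmelt_abort("allele-specific primer Tms are not populated", "invalid_input")
  }
  top <- max(tms)
  if (top < hrm_tm_range[1]) {
    snpmelt_abort(
      sprintf("max allele-specific primer Tm %.2f C is below the HRM window [%g, %g]; no routing rule applies",
              top, hrm_tm_range[1], hrm_tm_range[2]),
      "unroutable"
    )
  }
  if (top <= hrm_tm_range[2]) "HRM" else "AS-qPCR"
}

shared_3p_suffix <- function(a, b) {
  # length of the common 3' suffix of a and b, excluding the terminal base
  ca <- rev(seq_chars(a))[-1L]
  cb <- rev(seq_chars(b))[-1L]
  n <- min(length(ca), length(cb))
  s <- 0L
  for (i in seq_len(n)) {
    if (ca[i] == cb[i]) s <- s + 1L else break
  }
  s
}

#' Structural checks on a published allele-specific primer pair
#'
#' Validates the parts of the design rules that can be checked from the two
#' primer sequences alone (no template needed): 3'-terminal bases carry the
#' two alleles; the penultimate bases agree (both primers share the single
#' deliberate penultimate mismatch against the common template); and all
#' other differences between the primers, aligned from the 3' end, are
#' confined to the 5' half (the Tm-shifting introduced-mutation region).
#'
#' @param wild_primer,mutant_primer Primer sequences 5'->3' (whitespace
#'   tolerated).
#' @param ref_allele,alt_allele The alleles carried by the wild-type and
#'   mutant primers *on the primer strand* (for reverse-orientation primers
#'   pass the complemented bases).
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
check_primer_pair <- function(wild_primer, mutant_primer, ref_allele, alt_allele) {
  w <- gsub("\\s", "", toupper(wild_primer))
  m <- gsub("\\s", "", toupper(mutant_primer))
  check_dna(w, "wild primer"); check_dna(m, "mutant primer")
  lw <- nchar(w); lm <- nchar(m)
  term_ok <- substr(w, lw, lw) == toupper(ref_allele) &&
    substr(m, lm, lm) == toupper(alt_allele)
  pen_ok <- substr(w, lw - 1L, lw - 1L) == substr(m, lm - 1L, lm - 1L)
  s <- shared_3p_suffix(w, m)
  first_diff_dist <- s + 2L  # distance from 3' end of the nearest non-terminal difference
  conf_ok <- first_diff_dist > floor(min(lw, lm) / 2) ||
    s == min(lw, lm) - 1L
  region_detail <- sprintf(
    "matched 3' block %d nt; nearest non-terminal difference %d nt from 3' end",
    s + 1L, if (s == min(lw, lm) - 1L) NA_integer_ else first_diff_dist)
  tibble::tibble(
    check = c("terminal_allele", "penultimate_shared", "mutations_in_5p_half"),
    pass = c(term_ok, pen_ok, conf_ok),
    detail = c(
      sprintf("wild ends %s (ref %s), mutant ends %s (alt %s)",
              substr(w, lw, lw), ref_allele, substr(m, lm, lm), alt_allele),
      sprintf("penultimate bases %s / %s",
              substr(w, lw - 1L, lw - 1L), substr(m, lm - 1L, lm - 1L)),
      region_detail
    )
  )
}

#' Full compliance report for a designed triplet
#'
#' Re-derives the design-strand template from the target and itemizes every
#' design invariant: allele anchoring, the penultimate mismatch (exactly one,
#' differing from template), introduced-mutation classes (G/C raising vs A/T
#' lowering) and their confinement to the 5' half, an unmodified common
#' primer, opposite amplicon Tm shifts, the minimum amplicon Tm separation,
#' and identity of the two allele primers over their shared 3' region.
#' Always returns the report; nothing is thrown for a failing check.
#'
#' @param triplet A `primer_triplet`.
#' @param target The [snp_target()] it was designed for.
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
check_triplet <- function(triplet, target) {
  stopifnot(inherits(triplet, "primer_triplet"), inherits(target, "snp_target"))
  st <- design_strand(target, triplet$orientation)
  tmpl <- st$tmpl; pos <- st$pos
  cfg <- triplet$config %||% design_config()
  out <- list()
  add <- function(check, pass, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(check = check, pass = pass, detail = detail)
  }

  lw <- nchar(triplet$wild_primer); lm <- nchar(triplet$mutant_primer)
  add("wild_3p_allele",
      substr(triplet$wild_primer, lw, lw) == st$ref,
      sprintf("terminal %s vs ref %s", substr(triplet$wild_primer, lw, lw), st$ref))
  add("mutant_3p_allele",
      substr(triplet$mutant_primer, lm, lm) == st$alt,
      sprintf("terminal %s vs alt %s", substr(triplet$mutant_primer, lm, lm), st$alt))

  t_pen <- substr(tmpl, pos - 1L, pos - 1L)
  pen_w <- substr(triplet$wild_primer, lw - 1L, lw - 1L)
  pen_m <- substr(triplet$mutant_primer, lm - 1L, lm - 1L)
  add("penultimate_mismatch",
      pen_w != t_pen && pen_m != t_pen && pen_w == pen_m,
      sprintf("template %s, primers %s/%s", t_pen, pen_w, pen_m))

  for (side in c("wild", "mut")) {
    muts <- triplet[[paste0("introduced_mutations_", side)]]
    primer <- if (side == "wild") triplet$wild_primer else triplet$mutant_primer
    L <- nchar(primer)
    role <- triplet$roles[[if (side == "wild") "wild" else "mutant"]]
    class_ok <- if (role == "raising") all(muts$to %in% c("G", "C"))
                else all(muts$to %in% c("A", "T"))
    add(sprintf("%s_mutation_class", side),
        nrow(muts) >= 1L && class_ok,
        sprintf("%d %s mutations -> {%s}", nrow(muts), role, paste(muts$to, collapse = ",")))
    add(sprintf("%s_mutations_5p_half", side),
        all(muts$primer_pos <= floor(L / 2)),
        sprintf("positions %s of %d nt primer", paste(muts$primer_pos, collapse = ","), L))
  }

  common_tmpl <- revcomp(substr(tmpl, triplet$coords$common_start, triplet$coords$amplicon_end))
  add("common_primer_unmodified",
      identical(triplet$common_primer, common_tmpl),
      "common primer must match template exactly")

  # opposite Tm shifts relative to the unmodified allele amplicons
  unmod <- vapply(c(st$ref, st$alt), function(allele) {
    start <- if (allele == st$ref) triplet$coords$wild_start else triplet$coords$mut_start
    s <- substr(tmpl, start, triplet$coords$amplicon_end)
    s <- apply_subs(s, c(pos - start, pos - start + 1L),
                    c(triplet$penultimate$primer_base, allele))
    amplicon_tm(s, cfg$monovalent)
  }, numeric(1))
  shift_w <- triplet$amplicon_tms[["wild"]] - unmod[[1]]
  shift_m <- triplet$amplicon_tms[["mutant"]] - unmod[[2]]
  add("opposite_tm_shifts", shift_w * shift_m < 0,
      sprintf("wild shift %+.2f, mutant shift %+.2f", shift_w, shift_m))

  add("amplicon_separation",
      abs(diff(triplet$amplicon_tms)) >= cfg$min_separation - 1e-9,
      sprintf("|%.2f - %.2f| = %.2f >= %.2f", triplet$amplicon_tms[["wild"]],
              triplet$amplicon_tms[["mutant"]], abs(diff(triplet$amplicon_tms)),
              cfg$min_separation))

  s <- shared_3p_suffix(triplet$wild_primer, triplet$mutant_primer)
  half_min <- floor(min(lw, lm) / 2)
  add("shared_3p_region", s + 2L > half_min || s == min(lw, lm) - 1L,
      sprintf("matched 3' block %d nt (terminal excluded: %d)", s + 1L, s))

  dplyr::bind_rows(out)
}
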