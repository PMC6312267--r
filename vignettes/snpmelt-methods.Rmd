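---
title: "Methods: differentially melting amplicon genotyping in snpmelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentially melting amplicon genotyping in snpmelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmelt)
```

snpmelt implements genotyping by competitive amplification of differentially
melting amplicons (CADMA): a single three-primer reaction in which the two
allele-specific primers deliberately mutate their products so that the two
allele amplicons melt at different temperatures. This vignette documents the
models, the tunable parameters, the numerical choices, and what the bundled
simulator does and does not emulate.

## Thermodynamic models

**Primer Tm.** Primers use the unified nearest-neighbor model: stacking
enthalpies and entropies summed over dinucleotide steps, duplex-initiation
terms per terminal base, a symmetry correction for self-complementary
oligos, and a monovalent-salt entropy adjustment of 0.368 cal mol⁻¹ K⁻¹ per
phosphate pair. Defaults are 50 mM Na⁺-equivalent and 200 nM total oligo
(typical qPCR conditions); both are parameters of `oligo_duplex()`. The
parameter table ships as JSON (`load_nn_params()`) and can be replaced.

Two deliberate simplifications:

- **Mismatches** subtract a flat, configurable penalty (default 5 °C each)
  instead of using position- and identity-specific mismatch tables. The
  design algorithm only needs ranking and threshold behavior — "a mismatched
  primer binds noticeably weaker" — not accurate mismatch thermodynamics,
  and the flat penalty keeps that behavior monotone and auditable.
- **Routing uses the matched Tm of the final primer sequence.** From the
  second cycle onward the template is the previous cycle's product, which
  carries the introduced mutations, so the primers prime a perfect match for
  almost the entire run. Annealing temperatures and the HRM/AS-qPCR routing
  decision therefore use the fully matched nearest-neighbor Tm; the
  per-mismatch penalty applies only when a first-cycle primer-versus-genomic
  duplex is queried explicitly.

**Amplicon Tm.** Products use the empirical GC/length formula
Tm = 81.5 + 16.6 log₁₀[Na⁺] + 41 f_GC − 500/L. It is strictly increasing in
GC fraction at fixed length and indifferent to A↔T or G↔C swaps, which is
exactly the property the design exploits: each G/C introduced into a primer
raises its allele product's predicted Tm by 41/L degrees. Introduced
mutations are treated as fully incorporated — the input is the final product
sequence.

## Assay design

`design_triplet()` searches deterministically (fixed iteration order, first
feasible candidate), so a target plus a configuration always yields a
byte-identical triplet. The rules, in search order:

1. **Orientation.** Forward strand first, then reverse; the first orientation
   admitting a full design wins.
2. **Penultimate mismatch.** Both allele-specific primers share one
   deliberate mismatch at the second base from the 3′ end: a transversion of
   the template base, preferring the candidate that keeps the 3′ G/C clamp
   at three bases or fewer (a long clamp would blunt the discrimination the
   mismatch exists to sharpen). The template is silent on this choice;
   transversion-plus-clamp-guard is our tie-break.
3. **Common primer.** The nearest downstream position (≥ 30 nt from the SNP,
   `min_gap`) where an 18–30-mer has a matched Tm inside the primer window.
   Short amplicons are preferred: melt transitions are sharper and each
   introduced mutation moves the product Tm more.
4. **Raising vs lowering.** G/C (Tm-raising) mutations go to the allele
   whose unmodified amplicon melts lower, maximizing achievable separation;
   ties (alleles of equal GC class) go to the wild-type primer.
5. **Escalation.** For k = 1…4 mutations per primer (nearest-to-5′ eligible
   positions first, confined to the 5′ half so the 3′ half stays perfectly
   template-matched), primer lengths are chosen as the shortest with a
   matched Tm in the window, and the design is accepted once the predicted
   amplicon Tm separation reaches `min_separation` (default 1.5 °C — about
   three times the simulator's transition width, and comfortably resolvable
   on a 0.1 °C acquisition grid).

`route_method()` sends an assay to HRM when the hotter allele-specific
primer's Tm lies in [58, 60] °C and to AS-qPCR above 60 °C; exactly 60 °C is
HRM (the window is printed as a closed interval). Below 58 °C there is no
rule, and the function refuses rather than guesses. Annealing temperature is
reported as the minimum primer Tm rounded to the nearest degree — a
convention, not a reproduction of any published per-assay value.

`check_triplet()` re-derives the design-strand template and itemizes every
rule; `check_primer_pair()` applies the template-free subset (terminal
alleles, shared penultimate base, differences confined to the 5′ half) to
externally published primer pairs. The confinement bound uses the shorter
primer's half-length, since allele-specific primers of one assay may differ
in length.

## HRM calling

`normalize_melt()` fits a line to each of a pre-melt and a post-melt window
and rescales fluorescence as (F − post)/(pre − post), clipped to [0, 1].
Because both lines absorb any affine per-well transform, gain, offset and
linear baseline drift cancel exactly — this is what makes wells comparable.
Defaults are 72–76 °C and 90–94 °C, suitable for amplicons melting around
80–86 °C; `hrm_windows()` derives per-assay windows from a triplet's
predicted amplicon Tms (4 °C windows, 5 °C clear of the nearer transition),
which the plate pipeline uses. Windows with fewer than three points, or a
curve whose pre-melt level nowhere exceeds its post-melt level, are errors.

Classification is nearest-reference: mean-squared distance on a common
0.1 °C grid (linear interpolation) against normalized curves of
known-genotype controls from the same plate, averaged over their duplicate
wells. The commercial software used on the instrument is proprietary;
nearest-reference distance is a transparent surrogate, defensible because
the protocol always runs sequencing-confirmed controls of all three
genotypes alongside samples. Confidence is 1 − d_best/d_second; below the
ambiguity threshold (default 0.2) the sample is a no-call. Duplicate wells
are called independently and must agree — any disagreement or ambiguous
replicate is a no-call. How ambiguous duplicates were handled upstream is
not documented anywhere we could follow; requiring concordance is this
package's policy.

## AS-qPCR calling

`compute_cq()` fits a straight baseline over cycles 3–15 (configurable),
sets the threshold at 10 standard deviations of the baseline residuals
applied to the baseline-corrected signal (or uses a fixed raw-fluorescence
threshold), and interpolates the fractional crossing cycle linearly. A flat
zero-variance curve is an error under the automatic threshold (there is
nothing to scale against) and simply "no Cq" under a fixed one. The
10-SD-over-baseline construction is a widely used instrument convention; the
upstream thresholding method is unstated.

The dual-reaction rule: a reaction is positive for its allele when
Cq < cutoff, default 30. Both positive → het; one → the corresponding
homozygote; neither → no call. The rule as printed covers "< 30" and "> 30"
but not equality; Cq = 30.000 is classified **not positive** (strict <), and
since the cutoff was calibrated empirically upstream it is exposed as a
parameter rather than hard-coded. Duplicates must agree, as for HRM.

## The simulator

`simulate_cohort()` draws genotypes per group from specified frequencies
(multinomial, seeded); the default cohort shape is 55 cases and 110 controls,
the 1:2 design of the bundled example study. `simulate_melt()` renders
homozygotes as a single two-state helix-coil transition at their allele
amplicon's predicted Tm and heterozygotes as an equal-weight mixture of the
two transitions; `simulate_amplification()` renders logistic growth whose
nominal-threshold crossing falls uniformly in 24–27 cycles when the targeted
allele is present (plus one doubling time for heterozygotes, which start
from half the template), and either stays flat or amplifies late (Cq > 32,
2 % of reactions by default) when it is absent. Imperfections: additive
Gaussian noise of 0.5 % of plateau, per-well gain ±10 %, baseline drift up
to 0.1 % of plateau per °C, transition width 0.5 °C, efficiency 0.85–1 —
chosen so that default-noise calling is accurate but not by construction
perfect (gain and drift are removed exactly by normalization; only additive
noise and the Cq draw survive as error sources). Each sample emits duplicate
wells.

What the simulator does **not** emulate: heteroduplex species (CADMA
discrimination works through amplicon composition, and saturating-dye
heteroduplex signals are secondary), temperature calibration error across
the plate, probe chemistries, polymerase kinetics, and genotyping error
correlated with DNA quality. Passing the simulation-based tests therefore
demonstrates that the *algorithms* recover what the curves encode — not that
any instrument will achieve the same accuracy on degraded samples.

## Association statistics

Odds ratios are ad/bc against the reference genotype with Woolf log-normal
intervals, exp(ln OR ± z √(1/a + 1/b + 1/c + 1/d)); Woolf intervals
reproduce every interval printed for the bundled cohort exactly at printed
precision, which is how the upstream software's method was identified. Zero
cells take the Haldane–Anscombe +0.5 correction (flagged in output); a fully
zero diagonal is an undefined-OR error. Pearson χ² is the closed 2×2 form
without continuity correction, df = 1; p-values are recomputed rather than
copied — one p-value printed alongside the bundled counts (0.95 for the FTO
heterozygote row) is inconsistent with those counts (uncorrected Pearson
gives ≈ 0.095) and is treated as a misprint. The dominant model pools all
non-reference genotypes. Non-reference genotypes observed in neither group
are skipped; a locus with a single observed genotype yields an empty,
`monomorphic`-flagged report. No multiple-testing adjustment is applied by
default (the example study tested at a fixed 5 % level); `level` is the only
exposed knob.

**Display rounding.** Percentages are reported at full precision alongside a
one-decimal display value computed by two-stage rounding: to two decimals,
then half-to-even to one. This is the convention the bundled example tables
were printed with (72/110 = 65.4545… displays as 65.4); plain half-up
rounding would print 65.5. Statistics are rounded only at presentation.

## Problem sizes and tolerances in the test suite

Unit tests use closed-form or brute-force oracles frozen into the suite
(independent nearest-neighbor sums, analytic logistic crossings, mixture
curves evaluated directly). Concordance is assessed on simulated cohorts of
3 genotypes × 200 samples in duplicate — large enough that a 1 % error rate
would be visible, small enough to run in seconds — and statistical oracle
equivalence on 1000 random 2×2 tables at 10⁻⁹ relative tolerance.
Monte-Carlo recovery of the dominant-model odds ratio uses 5000 subjects per
group, where the sampling standard error of the log-OR is ≈ 4 %.
Normalization identities are asserted at 10⁻⁶ (plateau mapping), 10⁻⁹
(idempotence on exactly-piecewise-linear curves) and 10⁻⁹ (affine
invariance); the analytic-versus-interpolated Cq comparison allows 0.1
cycles, the linear-interpolation error at the test curve's steepness.

## Known limitations

- No secondary-structure (hairpin/cross-dimer) screening and no genome-wide
  specificity check; the design search is local to the provided flanks.
- The flat mismatch penalty cannot rank different mismatch identities at
  the same position.
- Design feasibility depends on local GC content: AT-rich neighborhoods may
  admit no primer reaching the 58 °C routing floor within 30 nt, and the
  search reports failure rather than relaxing constraints (~30 % of
  uniformly random 50 %-GC targets at defaults).
- The HRM classifier needs all three genotype controls on the plate; it
  does not cluster unsupervised.
- Association is single-locus; no covariates, Hardy–Weinberg testing, or
  haplotype estimation.
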