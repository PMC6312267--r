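# snpmelt

Low-cost SNP genotyping without probes or sequencing: **snpmelt** implements
the full workflow around three-primer allele-specific PCR with deliberately
mismatched primers — *competitive amplification of differentially melting
amplicons* (CADMA) — from assay design through raw-fluorescence genotype
calling to case-control association statistics. It is aimed at genetics labs
that genotype candidate SNPs on a real-time PCR machine with a saturating
intercalating dye, and at anyone who wants a transparent, scriptable
re-implementation of that workflow.

## The method

For a biallelic SNP with alleles *R*/*A*, three primers are designed:

- a **wild-type-specific** and a **mutant-specific** primer, each anchoring
  its 3′-terminal base on one allele, each carrying a deliberate mismatch at
  the second base from the 3′ end (sharpening allelic discrimination), and
  each carrying extra mutations in its 5′ half — G/C mutations that *raise*
  the melting temperature of one allele's product, A/T mutations that *lower*
  the other's;
- a **common** primer, unmodified template, closing the amplicon.

Because the introduced mutations are copied into the product from the second
cycle onward, the two allele amplicons differ in base composition and melt
apart. Primer Tm (unified nearest-neighbor model,
Tm = ΔH / (ΔS + R ln(C_T/4)) − 273.15 with a monovalent-salt entropy term)
routes each assay: allele-specific primers melting in 58–60 °C are read by
**high-resolution melting** (HRM) in a single tube; hotter primers by two
**allele-specific qPCR** (AS-qPCR) reactions. Amplicon Tm uses the empirical
GC/length model Tm = 81.5 + 16.6 log₁₀[Na⁺] + 41 f_GC − 500/L.

Genotypes are called from raw plate fluorescence:

- **HRM**: melt curves are normalized between pre- and post-melt windows
  (line fits; per-well gain, offset and linear drift cancel exactly) and
  classified by mean-squared distance against known-genotype control curves
  run on the same plate. Heterozygotes melt as an equal-weight mixture of the
  two allele transitions.
- **AS-qPCR**: the quantification cycle Cq (baseline-fit threshold crossing)
  of each allele's reaction decides presence — both Cq < 30 → heterozygous,
  one Cq < 30 → homozygous for that allele, neither → no call. Every sample
  runs in duplicate wells; discordant duplicates are no-calls.

Association uses 2×2 tables against the reference genotype: odds ratios
OR = ad/bc with Woolf 95 % intervals exp(ln OR ± 1.96 √(1/a+1/b+1/c+1/d)),
uncorrected Pearson χ², and a dominant model pooling variant carriers.

A seeded simulator generates cohorts at specified genotype frequencies and
instrument-like melt/amplification traces, so the entire pipeline is testable
without an instrument.

## Worked example

The package bundles genotype counts from a PCOS case-control cohort
(55 cases, 110 controls, seven reproductive-axis SNPs) genotyped with these
assays:

```r
library(snpmelt)
library(dplyr)

counts <- pcos_genotype_counts()
fit <- association_report(filter(counts, rsid == "rs9939609"))
fit
#> <snp_assoc> rs9939609  (55 cases, 110 controls)
#>   AT vs TT       OR    2.035  (95% CI    0.877 -     4.72)  p 0.095
#>   AA vs TT       OR     5.28  (95% CI     2.32 -   12.016)  p 3.5e-05
#>   AT+AA vs TT    OR    3.316  (95% CI    1.687 -    6.515)  p 0.00039
```

The AA genotype of FTO rs9939609 is strongly associated with case status
(OR 5.28, CI excludes 1); so is carrying any A allele (dominant model,
OR 3.316). `tidy(fit)` returns the same numbers as a tibble, `glance(fit)` a
one-row summary, and `autoplot(fit)` a forest plot.

Designing an assay for a new SNP takes a target with ~120 nt flanks:

```r
set.seed(101)
fl <- function(n) paste(sample(c("A","C","G","T"), n, TRUE,
                               prob = c(0.225, 0.275, 0.275, 0.225)), collapse = "")
tg <- snp_target("rs_example", fl(120), fl(120), "C", "T")
design_triplet(tg)
#> <primer_triplet> rs_example (reverse strand, method AS-qPCR)
#>   wild   (G) ATTTATACTCCACGCAGACCTGAGGAG  Tm 59.30
#>   mutant (A) CCGCGCGGGCCTGAGGAA  Tm 64.12
#>   common     TAAGCCTATAAACAGGCCTATCCAGCC  Tm 59.34
#>   amplicon Tms 73.46 / 75.93 (separation 2.47), annealing 59 C
```

The mutant primer's Tm (64.1 °C) is above the HRM window, so the assay routes
to AS-qPCR. `check_triplet()` itemizes every design rule for any triplet;
`simulate_experiment()` + `call_hrm_plate()` / `call_qpcr_plate()` run the
whole calling pipeline on synthetic plates.

A command-line interface wrapping the same functions ships in
`inst/cli/snpmelt.R` with subcommands `design`, `simulate`, `call-hrm`,
`call-qpcr` and `assoc`.

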