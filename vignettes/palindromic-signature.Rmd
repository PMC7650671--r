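---
title: "Palindromic core-motif mutation signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Palindromic core-motif mutation signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palinsig)
```

## The biological model

Bladder tumors carry recurrent *non-coding* somatic mutations at a small
family of genomic loci sharing one structure: a 6-bp core motif (TGAACA at
most loci; AGATCA in intron 10 of RAD51B) flanked on both sides by a
perfect palindromic arm — the left arm is the reverse complement of the
right arm, so the region can fold into a DNA hairpin with the core in the
loop. The recurrently mutated bases are the internal G and C of the core
(0-based offsets 1 and 4, hence genomic positions exactly 3 bp apart).
Read on the strand where the mutated base is a pyrimidine, these events are
C>T at a TCA trinucleotide (the core G, whose forward context TGA is the
reverse complement of TCA) and C>T at ACA (the core C). TCA is the optimal
substrate of the APOBEC3 cytidine deaminases, whose activity produces
COSMIC single-base-substitution signature SBS2; hairpin loops expose
single-stranded DNA and concentrate APOBEC editing. The package models
this structure end to end: locus discovery in a reference, cohort-level
mutation matrices, the association statistics used on such cohorts, context
classification, and qPCR expression quantification for the APOBEC3 genes.

## Locus definition and the scanner

A locus is an occurrence of the core (on either strand of the reference,
always reported in forward coordinates) together with its **maximal** arm
length: the largest *k* such that the *k* bases immediately left of the
core equal the reverse complement of the *k* bases immediately right of it.
Choices a scanner must make, and the ones made here:

* **The core is excluded from the palindrome.** TGAACA is not
  self-complementary; the arms are measured strictly outside it. This
  matches the description of the core as *flanked by* palindromic
  sequences, and makes the arm length well defined for any core.
* **Arms are perfect.** No mismatches, bulges, or thermodynamic scoring —
  the discovery procedure this reimplements is an exact pattern search.
  Anything involving folding energies is out of scope.
* **N never matches.** An unknown base cannot be declared palindromic, so
  any N stops arm extension and N-containing core windows are skipped.
* **Case-insensitive matching, case-aware filtering.** Soft-masked
  (lowercase) bases participate in matching, but each locus reports its
  lowercase fraction over the full footprint (arms + core);
  `passes_repeat_filter()` with threshold 0 (the default) keeps only loci
  entirely outside repeat-annotated sequence. Soft-masking replaces an
  external repeat-annotation track, keeping the package self-contained.
* **Homopolymer arms are artifacts.** A poly-A arm is "palindromic"
  against a poly-T arm but reflects a low-complexity run, not a hairpin;
  the variant-window mode always removes candidates whose pattern or
  either arm is a homopolymer, and the genome-wide mode does so by default
  (configurable, since the published filter is stated only for the
  variant-window search).
* **Thresholds.** "Longer than 7 bp on each side" is implemented as
  `min_arm = 8` in the variant-window mode; the genome-wide search for
  arms "of 9, 10, or 11 bp" is `min_arm = 9`, `max_arm = 11`, both
  configurable because it is not stated whether loci with arms ≥ 12 were
  excluded or simply absent.
* **Coordinates.** All R-side coordinates are 1-based inclusive — the host
  language's convention, and the one the published positions
  (chr11:10331381/10331384, chr15:27617168/27617171) use. BED output
  converts to 0-based half-open at the writing boundary; nothing else
  does coordinate arithmetic.

Overlapping core occurrences are each reported; only identical intervals
(a self-complementary core matching in both orientations) are collapsed.
The scanner's correctness is checked against an independent quadratic
brute-force oracle (every position × every depth, by substring comparison)
and by exact recovery of implanted loci in synthetic genomes.

## The cohort model

The registry names each assayed locus and its two mutable positions;
`build_matrix()` is deliberately strict (unknown positions and unknown
samples are errors, duplicates warn) because silent dropping of calls is
the classic failure mode of this step. The matrix is binary per locus — a
sample mutated at both core positions scores 1 — because every downstream
statistic is per-locus binary; alleles are retained in a side table for
context classification. Published coordinates exist for only four loci;
the remaining registry entries carry clearly flagged synthetic placeholder
coordinates (`synthetic_coord` column) and real analyses are expected to
supply their own registry.

Samples are stratified by burden over the 18 TGAACA loci into groups
G1 (0), G2 (1–2), G3 (≥3) — the published grouping, with sizes 39/46/18
in the study cohort.

## Association statistics and the selection rule

The published analyses report plain chi-square, Yates-corrected chi-square
and two-sided Fisher exact p-values without stating the rule that chose
among them. The rule implemented by `select_and_run_test()` — plain
chi-square when every expected count is ≥ 5, Yates when every expected
count is ≥ 3 but some are < 5, Fisher otherwise — is the unique simple
minimum-expected-count rule consistent with *all* the verifiable printed
p-values (0.021 plain at min E ≈ 13.7; 0.0007 and 0.035 Yates at
min E ≈ 3.50 and 3.65; 0.0004 and 0.045 Fisher at min E ≈ 0.93 and 2.33;
0.028 plain at min E ≈ 5.83). Both thresholds are arguments.

Numerical conventions: the Yates term is floored so a corrected deviation
cannot cross zero; the two-sided Fisher p-value uses the point-probability
rule (sum of all tables with the observed margins whose probability does
not exceed the observed one), which reproduces the printed 0.0004 and
0.045 where tail-doubling would not; zero-margin tables are degenerate
(p = 1, flagged) rather than errors in the pairwise driver. The
computations are delegated to R's `chisq.test`, `fisher.test`,
`kruskal.test` and `wilcox.test`; the test suite cross-checks them against
closed-form statistics and exhaustive hypergeometric enumeration, so the
selection rule — the part that is actually new — sits on audited ground.
No multiple-testing correction is applied anywhere (the published analysis
reports raw p-values); a Bonferroni column is emitted for reference only.
Significance language throughout uses two-sided α = 0.05.

## Expression quantification

Relative expression is 2^(Ct_ref − Ct_gene) with TBP as the default
endogenous reference, assuming 100% amplification efficiency (exact
doubling; no standard-curve calibration, no multi-reference geometric
averaging). Replicate Ct values are averaged arithmetically before the
difference. Each gene is then rescaled so the median over the designated
normal-tissue cohort equals exactly 1 (midpoint convention for even
counts); the number and identity of normals is an input, not a constant,
since the published normal count is reported inconsistently (19 vs 20).
Failed measurements stay missing — a sample lacking the reference gene is
skipped with a warning rather than imputed as zero.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults are the study's stated conditions wherever one
is stated.

**Genomes.** Implants are `arm + core + reverse_complement(arm)`
constructs at recorded positions, flanked by A/A pairs (which cannot
extend a palindrome), so the measured arm equals the implanted arm
exactly. Decoy classes — bare cores, homopolymer-armed constructs,
soft-masked (lowercase) constructs — exercise each filter separately.
Background is i.i.d. uniform DNA; at the arm lengths of interest (≥ 8) a
spurious qualifying locus has probability ~4^-14 per position, so truth
tables remain exact at the simulated scales.

**Cohorts.** Mutation calls are correlated Bernoulli draws driven by one
per-sample latent factor: `logit P(call at locus j) = alpha_j + sigma·z`,
`z ~ N(0,1)`. A single shared factor is the simplest structure producing
the observed *all-positive* pairwise associations, and corresponds to the
motivating idea of a common per-tumor instability level. `alpha_j` is
calibrated by 1-D root finding (Gaussian quadrature of the logistic-normal
integral) so each locus hits its marginal — defaults are the published
frequencies (45.6%, 29.1%, 11.7%, 9.7%, 7.8%, 6.8%, 1%, 1%; the ten
unnamed panel loci default to 2%, the order of magnitude of the rarer
assayed loci). `sigma` is calibrated so the model-implied odds ratio
between Intron ADM and PLEKHS1 equals 10, the value of the published 2×2
(70·9 / 21·3). RAD51B calls are drawn conditionally on TGAACA positivity
(conditional probability 5/64 by default), reproducing the observed
nesting; covariates are drawn per group from the published group-wise
proportions, and outcome fields are carried but not modelled. Calls are
assigned to core offset 1 (G>A) or offset 4 (C>T) with probability 0.5
each — both positions are reported mutated at comparable rates.

**Expression.** Log-normal on the log2 scale: normals at level 1, tumor
baseline 10× normal (the order of the published APOBEC3B medians), group 3
shifted by the configured fold (default 2). The scatter default
`sd_log2 = 1` (≈ 2-fold biological variability) is a typical qPCR
between-tumor dispersion; Ct values are generated by inversion
(`Ct_gene = Ct_ref − log2(expression)`), so quantification recovers the
generated expression exactly, making the round trip testable to machine
precision.

What the generators do **not** emulate: chromatin- or replication-timing-
dependent mutation rates, sequence-context-dependent background mutation,
allele fractions, measurement noise in Ct replicates, and covariate
correlations beyond the group effects. Passing tests therefore establish
the pipeline's correctness and calibration under the stated statistical
structure, not the biological fidelity of that structure.

## Validation scales

The suite checks: exact oracle agreement on 200 random sequences up to
5 kb; 100% sensitivity and precision on 55 implants (arms 8–12) with
decoys; marginal recovery within 3 binomial SE and odds-ratio recovery
inside its 95% CI at n = 10,000 simulated samples; uniformity of
co-occurrence p-values under independence (Kolmogorov–Smirnov at α = 0.01,
2,000 replicates of n = 10,000); type-I error of the chi-square tests
within 3 Monte-Carlo SE of 0.05 in their validity regimes (n = 500 plain;
n = 10,000 Yates, where the half-count correction is negligible) and
conservatism of Fisher at n = 40; and Kruskal–Wallis power above 80% for
the 2-fold group-3 shift at group sizes 39/46/18 (observed ≈ 92%). These
sizes keep the full suite under a minute while leaving Monte-Carlo error
well below the tolerances tested.

## Known limitations

* Arm measurement is exact-match only; biologically plausible near-perfect
  hairpins (one mismatch, small bulges) are not detected.
* The genome-wide locus count on hg19 depends on unstated definitional
  details (treatment of arms ≥ 12, filter ordering), and verifying it
  requires a local ~3 GB soft-masked reference
  (`options(palinsig.hg19 = ...)`).
* SBS2 membership is approximated by trinucleotide-context classes, not by
  signature deconvolution against the COSMIC catalogue.
* The latent-factor cohort model produces exchangeable positive dependence;
  it cannot represent negative or locus-pair-specific association
  structure.
* Survival analysis is deliberately absent: the published outcome analyses
  report no effect, and reproducing "no difference" adds no testable
  quantity.
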