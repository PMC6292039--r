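---
title: "Methods: dissecting heterosis and inbreeding depression with RIL-derived populations"
author: "hetqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting heterosis and inbreeding depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetqtl)
```

## The experimental design this package models

A biparental cross between two inbred cotton lines (P1 and P2) is taken
through repeated selfing to a panel of recombinant inbred lines (RILs,
F8 here). Three hybrid populations are then reconstructed from the same
panel:

* an **immortalized F2 (IF2)**: RILs pair-crossed by random permutation
  in two rounds, every RIL serving once as female and once as male per
  round (188 RILs give 376 hybrids);
* two **Design-III backcross populations**: every RIL crossed to each
  original parent (HSBCF1 with recurrent P1, MARBCF1 with recurrent
  P2).

Because RILs are (almost) homozygous, the genotype of every hybrid
follows marker-by-marker from its parents' genotypes, so only the RILs
need genotyping. Each population is phenotyped for six yield traits (FB,
BN, BW, LP, SY, LY) in several environments with replicated plots.

Two derived datasets isolate the non-additive signal:

* **hybrid breakdown** of a RIL, `HB = RIL − MP`, with
  `MP = (P1 + P2)/2` the midparent in the same environment — a
  component of inbreeding depression;
* **mid-parent heterosis** of a hybrid, `MPH = F1 − MP`, with MP the
  mean of the hybrid's own parents in that environment.

At a biallelic locus with genotype score `x` (number of P1 alleles
minus 1) and heterozygosity indicator `z`, the additive effect is
`a = (P1P1 − P2P2)/2` and the dominance effect
`d = P1P2 − (P1P1 + P2P2)/2` on genotype-class means. An IF2 or
RIL+MPH locus with dominance degree `|d/a| <= 1` is called partially or
completely dominant (PD/D), with `|d/a| > 1` over-dominant (OD); a
backcross locus is judged by `2|d|` (from MPH) against the composite
backcross contrast `|a + d|`. The MPH value of a hybrid contains only
the dominance contribution of each locus (`MPH = sum(d z) + ...`), so a
scan of MPH values tests the heterozygote-versus-homozygote-mean
contrast directly.

## The synthetic-data generator

Nothing downstream depends on real field data: the
`simulateMap()` / `simulateRilGenotypes()` / `simulatePhenotypes()`
chain generates complete studies with a known truth
(`emitTruthLedger()`).

* **Genomes.** Defaults approximate a dense intraspecific SNP map:
  2618 markers over 26 chromosomes, evenly spaced, 150 cM per
  chromosome. The Haldane map function (no crossover interference)
  converts interval lengths to crossover probabilities; Kosambi is
  available but nothing here assumes it.
* **Lines.** Selfing is simulated explicitly, one meiosis per
  chromosome per generation with independent interval crossovers, for
  `selfingGenerations = 7` after the F1. This leaves the residual
  heterozygosity real F8 lines have, `(1/2)^7 ≈ 0.78%` per locus,
  rather than using the algebraic RIL shortcut.
* **Hybrids.** `deduceHybridGenotypes()` applies the deduction rules;
  a missing or residually heterozygous RIL call makes the hybrid call
  missing (hard calls only — heterozygous F8 calls are too rare to
  justify probabilistic propagation).
* **Phenotypes.** `value = mu_e + sum(a x + d z + qe_e x) +
  sum(aa x1 x2 + ad x1 z2 + da z1 x2 + dd z1 z2) + GE + eps`, with a
  line-by-environment deviation shared by replicates and an i.i.d.
  residual per plot. Defaults in `demoArchitecture()` use environment
  means and noise scales typical of cotton yield trials (boll weight
  near 6 g, lint percentage near 38%, plot seed-cotton yield in the
  hundreds); these scales are deliberate but arbitrary — no published
  phenotype-model parameters exist to calibrate against. Trait clamps
  (e.g. percentages in (0, 100)) are off by default so the linear
  model stays exact in tests.

What the generator does **not** emulate: selection during line
development, segregation distortion, crossover interference,
multi-allelic loci, and the long-range LD structure of natural
populations. Tests passing on these simulations therefore validate the
estimation machinery under its own assumptions, not robustness to
those violations.

## Genome scans

`genotypeProbabilities()` converts each population into expected
genotype-class probabilities on a cM grid (default step 1 cM),
conditioning on the nearest informative flanking markers. Internally
every population is one or two two-state Markov chains along the
chromosome: one chain for a RIL genome, one for the RIL-derived gamete
of a backcross hybrid, and two exchangeable chains for an IF2 hybrid
(a heterozygous call constrains the unordered pair; the two pairings
of left and right flank phases are weighted by their whole-interval
transition probabilities). At a typed marker the probabilities
collapse to an indicator; with no informative marker on a chromosome
they fall back to the population prior.

`cimScan()` is Haley–Knott regression of the replicate-averaged
phenotype on the expected scores, plus background marker cofactors:

* cofactors are chosen by forward stepwise regression (entry p = 0.01,
  at most 10), and dropped within a 10 cM window around the tested
  position; all three values are conventional and configurable;
* `LOD = (n/2) log10(RSS0/RSS1)`; a perfect fit is capped at 50 to
  keep profiles finite;
* the regressors follow the dataset: additive score for RIL values,
  additive + dominance for IF2 values, the composite
  heterozygote-minus-recurrent-homozygote contrast for backcross F1
  values, and the dominance contrast alone for MPH datasets;
* the genome-wide threshold is the 95th percentile of the maximum LOD
  over phenotype permutations (protocol: 1000 permutations, step
  1 cM); cofactor selection is not re-run per permutation.

One calibration fact worth stating plainly: with cofactors selected
from the observed phenotype and held fixed under permutation, the
procedure is anticonservative — on null simulations we measure a
genome-wide type-I error near 0.12 instead of 0.05, because a
spuriously selected marker is excluded from the model inside the
window around nearby positions and its chance association resurfaces
as a local peak. This is a long-known property of
composite interval mapping, not of this implementation; the
calibration test suite therefore measures the threshold machinery on
scans without cofactors, where the empirical error rate is 0.05–0.06.

`callQtls()` turns contiguous supra-threshold runs into QTLs (peak
position, 1-LOD support interval — "support interval" is defined
nowhere more precisely in common practice, and 1-LOD is the
conventional choice). `mergeQtls()` merges records across datasets
and environments when support intervals overlap (transitively), counts
distinct dataset-by-environment detections as a stability score
(stable at >= 2 by default — "more than two" readings of stability
exist; the threshold is configurable), and names loci
`q<trait>-<chrom>-<k>` by position.

## Gene-action classification

`classifyIf2()` and `classifyBcf1()` implement the decision rules as a
total function of (detection pattern, effect estimates); every
combination yields exactly one outcome, including `"none"` for loci
with no hybrid-dataset detection. Decisions that required
interpretation:

* the boundary `|d/a| = 1` exactly is PD/D;
* `a = 0` with `d != 0` is treated as infinite dominance degree, hence
  OD; `a = d = 0` cannot occur for a detected locus;
* a locus present in backcross, MPH and RIL datasets is judged by the
  case-1 inequality `2|d| > |a + d|` (the "ratio of effects" rule);
* a locus detected in the RILs and a backcross but in no MPH dataset
  shows no dominance signal and is classified additive, the same as a
  backcross-only locus;
* "uncertain" requires detections in at least two environments with
  per-environment verdicts on both sides of the boundary; a locus seen
  once cannot be uncertain. The same rule is applied to all three
  hybrid populations.

`summarizeClasses()` reports per-population counts and percentages
(uncertain loci stay in the denominator, two decimals), with optional
pooling of the two backcross populations.

## Multi-environment analysis

`mqtlScan()` re-implements the two-stage inclusive-composite-interval
idea as stepwise background selection (entry `PIN = 1e-4` on
environment means) followed by a position-wise joint fit across
environments, `y_ie = mu_e + a x_i + (ae)_e x_i + cofactors`, with the
LOD computed over the stacked observations. Exact numerical agreement
with any proprietary implementation is a non-goal; the statistical
contract (type-I error, recovery, exact variance bookkeeping) is what
the tests pin down.

Variance percentages are sequential sums of squares over the **total
phenotypic SS** of the stacked data (whether such percentages should
be of phenotypic or genetic variance is ambiguous in common usage;
total phenotypic SS is used here and stated on every output):
`PV(A)` from adding the pooled locus term, `PV(AE)` from adding its
environment interaction. On balanced data
`PV(env) + PV(A) + PV(AE) + residual% = 100` exactly, which the suite
checks to 1e-8.

`eqtlScan()` fits all position pairs on a coarser grid (default step
5 cM; within-chromosome pairs closer than 20 cM are excluded to avoid
collinearity between linked scores): both main effects and their
environment interactions form the null, the epistatic product block
and its environment interactions the alternative. For two-class
RIL-derived data the block is the additive-by-additive product; for
IF2 classes the dominance scores and all four products (aa, ad, da,
dd) enter. `PV(AA)` and `PV(AAE)` are the corresponding sequential SS
percentages. The threshold permutes individuals and takes the 95th
percentile of the maximum epistatic LOD (200 permutations by default
at desk scale). Because a strong interaction lifts a whole ridge of
neighbouring pairs over the threshold, declared pairs are grouped into
connected ridges (neighbours within 10 cM on both loci, in either
locus order) and each ridge reports its maximum — one record per
interaction.

`classifyEpistasisType()` types each pair by how many of its loci lie
within 5 cM (the e-QTL grid step; no published convention exists) of
an m-QTL peak for the same trait and dataset: both = I, one = II,
neither = III. `congruence()` declares a single-locus QTL and an m-QTL
congruent when the m-QTL peak falls inside the single-locus support
interval on the same chromosome; one interval may harbor several
m-QTLs from different datasets.

## Variance components and heritability

`estimateComponents()` uses the balanced two-way ANOVA moment
estimator: `V_e = MS_error`, `V_GE = (MS_GE − MS_error)/r`,
`V_G = (MS_G − MS_GE)/(re)`, negatives truncated to zero. Under
balance this coincides with MINQUE(1), so nothing is lost relative to
the more elaborate estimator the formula is usually paired with; the
reported quantity, `H2 = V_G / (V_G + V_GE/e + V_e/(re))`
(`broadSenseH2()`, in percent), depends only on the components.
Unbalanced layouts are reduced to complete genotype-by-environment
cells with a warning; a single replicate confounds `V_e` with `V_GE`
and is reported as `V_e = 0` with a warning.

The package bundles a published cotton variance-component table
(`inst/extdata/cotton_varcomp_table.csv`) as a worked input. Recomputing
`H2` from the printed components reproduces the printed values to two
decimals for 12 of the 24 population-by-trait cells, is off by a
rounding digit (0.01–0.05) for eight, and disagrees for all four
HSBCF1 rows — those are internally inconsistent with the formula as
printed (they match only if `V_e/(re)` is replaced by `V_e/e`). The
exact-reproduction tests and the acceptance script use only cells that
verify.

## Pipeline, determinism and problem sizes

`runPipeline()` chains simulate → derive → scan → classify → multienv
→ varcomp → report, writing tidy CSVs and a JSON manifest with an MD5
checksum per file; the same configuration and seed reproduce every
checksum. Each stochastic stage derives a named child seed from the
master seed, so disabling one stage leaves the others' randomness
untouched. The default configuration is a demonstration-scale study —
5 chromosomes × 20 markers, 100 RILs, two traits — chosen to finish in
a few minutes; full study scale (26 × ~100 markers, 188 RILs, all six
traits) is a configuration change, not a code change.

The statistical test suite uses the same demonstration genome with
400 null studies (200 permutations each) for threshold calibration,
200 replicate studies at n = 188 and per-environment locus
heritability 0.1 for detection and localization, 200 replicates for
gene-action recovery, and n = 10000 lines where a binomial expectation
is checked to three standard errors. These sizes are the package's
choices for tight Monte-Carlo bounds at desk scale.

## Known limitations

* Haley–Knott regression approximates mixture interval mapping; with
  high missingness or sparse maps its effect estimates are mildly
  attenuated relative to EM-based fitting.
* Scans assume hard, essentially complete hybrid genotypes deduced
  from inbred parents; probabilistic propagation of residual parental
  heterozygosity is not modelled.
* No kinship or polygenic-background correction: the populations
  modelled here are balanced crosses where marker cofactors are the
  conventional control.
* Dominance cofactors are not used; background control is additive
  only.
* Pseudo-overdominance (repulsion linkage of dominant loci) is
  indistinguishable from true over-dominance at single-locus
  resolution, and no attempt is made to deconvolve it.
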