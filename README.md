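# hetqtl

Genetic dissection of **heterosis** and **inbreeding depression** for
quantitative traits — yield and yield components of upland cotton are
the motivating case — across four related mapping populations derived
from one biparental cross: recombinant inbred lines (RILs), an
immortalized F2 (IF2, RILs pair-crossed in two permutation rounds), and
the two Design-III backcross populations (every RIL crossed to each
original parent).

The package is for quantitative geneticists who want the whole chain as
tested, scriptable functions:

* a forward **simulator** of single-seed-descent RIL genomes (explicit
  selfing, Haldane map function) and multi-environment replicated
  phenotypes under a configurable QTL architecture, with a truth
  ledger for recovery tests;
* marker-wise **deduction of hybrid genotypes** from RIL genotypes and
  construction of the hybrid-breakdown (`HB = RIL − MP`) and
  mid-parent-heterosis (`MPH = F1 − MP`) datasets;
* **composite-interval-mapping scans** (Haley–Knott regression with
  stepwise background cofactors, genome-wide permutation thresholds,
  1-LOD support intervals, `q<trait>-<chrom>-<k>` naming, cross-dataset
  merging);
* **gene-action classification** of each locus from
  `a = (P1P1 − P2P2)/2`, `d = P1P2 − (P1P1 + P2P2)/2` and the dominance
  degree `|d/a|`: additive (A), partial/complete dominance (PD/D,
  `|d/a| ≤ 1`), over-dominance (OD, `|d/a| > 1`, with the three
  backcross OD rules and the MPH-only rule), or uncertain across
  environments;
* **multi-environment scans**: main-effect QTLs (m-QTLs) with the
  phenotypic variance split into main (`PV(A)`) and
  QTL-by-environment (`PV(AE)`) parts, two-locus epistatic pairs
  (e-QTLs, `PV(AA)`/`PV(AAE)`), epistasis types I/II/III by
  coincidence with m-QTLs, and congruence of m-QTLs with single-locus
  support intervals;
* **broad-sense heritability** from the balanced ANOVA variance
  components, `H² = V_G / (V_G + V_GE/e + V_ε/(re))`;
* a one-call **pipeline** (`runPipeline()`) with per-stage child
  seeds, CSV outputs, publication-style tables and a checksummed
  manifest.

## Worked example

Heritability of fruit branches per plant in a RIL trial, from its
variance components over 4 environments × 2 replicates:

```r
library(hetqtl)
broadSenseH2(0.287, 0.000, 1.804, e = 4, r = 2)
#> [1] 56
```

56% of the variance of RIL line means is genetic. Now simulate a small
study — 120 RILs, 3 chromosomes × 15 markers, one seed-cotton-yield
QTL (a = 28, d = 10 at 40 cM on C02, plot SD 60) — and scan it:

```r
map  <- simulateMap(nChrom = 3, nMarkers = 45, chromLength = 90)
cfg  <- simConfig(nRil = 120, seed = 4)
rils <- simulateRilGenotypes(map, cfg)
arch <- qtlArchitecture(
  loci = data.frame(trait = "SY", chrom = "C02", pos = 40, a = 28, d = 10),
  envMeans = matrix(720, 1, 4, dimnames = list("SY", paste0("E", 1:4))),
  sigmaE = 60)
pheno <- simulatePhenotypes(rils, arch, cfg)
probs <- genotypeProbabilities(rils, step = 1)
set.seed(1)
prof <- cimScan(pheno, probs, "SY", environment = "E1", nPerm = 500)
prof
#> ScanProfile [RIL/SY/E1]: 273 positions, max LOD 10.28, threshold 2.32
callQtls(prof)
#>        name dataset trait environment chrom peak lo hi      lod      pve
#> 1 qSY-C02-1     RIL    SY          E1   C02   42 38 47 10.27554 32.58742
#>          a  d composite favorable
#> 1 27.44467 NA        NA        P1
```

The scan recovers one QTL, `qSY-C02-1`: peak LOD 10.3 at 42 cM (true
position 40 cM inside the 1-LOD support interval [38, 47]), explaining
33% of the phenotypic variance, with the additive effect estimated at
27.4 (true 28) and the favorable allele from parent P1. RIL values
cannot estimate `d`; dominance comes from scanning the IF2 or the MPH
datasets (see the methods vignette in `vignettes/`).

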