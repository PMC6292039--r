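Package: hetqtl
Title: QTL Dissection of Heterosis and Inbreeding Depression in
    RIL-Derived Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic basis of heterosis and
    inbreeding depression for quantitative traits across related mapping
    populations derived from a biparental cross: recombinant inbred lines
    (RILs), an immortalized F2 made by pair-crossing RILs, and the two
    Design-III backcross populations. Provides a forward simulator of
    single-seed-descent RIL genomes and multi-environment phenotypes under
    a configurable QTL architecture; deduction of hybrid genotypes from
    RIL genotypes; hybrid-breakdown and mid-parent-heterosis datasets;
    composite-interval-mapping genome scans with permutation thresholds;
    classification of gene action at detected loci into additive, partial/
    complete dominance and over-dominance; multi-environment main-effect
    and two-locus epistatic scans with QTL-by-environment variance
    partitioning; broad-sense heritability from variance components; and
    an end-to-end pipeline with publication-style summary tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
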