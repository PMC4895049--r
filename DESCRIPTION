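Package: ecoscan
Title: Population-Genomic Scans for Ecotype Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of recent ecotype
    radiations shaped by sequential founder bottlenecks, such as killer
    whale ecotypes. Implements derived-mutation TMRCA estimation from
    third-codon transitions and transversions, windowed differentiation
    landscapes (Hudson FST, Dxy, nucleotide diversity), population branch
    statistic (PBS) selection scans with category and gene-set enrichment
    tests, ABBA-BABA D-statistics and three-population f3 tests with block
    jackknife errors, masking and polarization bookkeeping, and X-versus-
    autosome mutation-rate scaling. Ships a structured-coalescent cohort
    simulator (founder bottlenecks, expansions, admixture pulses, annotated
    genomic categories, sweep-like frequency displacements) used for
    calibration and power checks, and a deterministic end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
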