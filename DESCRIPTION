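Package: poolsweep
Title: Genome Scans for Selective Sweeps and Balancing Selection from
    Pooled and Individual Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for empirical genome scans that combine within-population
    polymorphism estimated from pooled sequencing with among-species
    differentiation estimated from individually genotyped samples. Implements
    pooled minor-allele-frequency estimation directly from allele read counts
    with depth and singleton filters, per-site Weir-Cockerham variance
    components and windowed (ratio-of-sums) F_ST, sliding-window aggregation,
    a joint two-variable quantile-tail outlier scan that merges consecutive
    outlier windows into sweep and balancing-selection candidate regions with
    gene annotation, and an identity-by-state neighbor-joining phylogeny with
    pseudodiploid coding of population pools and site-bootstrap supports. A
    synthetic-data module simulates multi-species pooled and individual
    resequencing datasets with planted selection regions and a known species
    tree for power evaluation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
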