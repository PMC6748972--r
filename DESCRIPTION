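Package: invpopkit
Title: Population-Genetic Analysis of Polymorphic Chromosomal Inversions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of polymorphic
    chromosomal inversions genotyped in human population panels: linkage
    between inversions and nearby variants (tag discovery, fixed/shared
    classification, non-recombining flank definition), haplotype clustering
    and minimum recurrence-event inference, divergence-based inversion
    dating with bootstrap confidence intervals, ascertainment-aware
    frequency analysis with detection-process simulation and robust
    stepwise regression, selection scans (Weir-Cockerham FST with matched
    empirical nulls, linked-site frequency-spectrum neutrality tests with
    Edgington combination, NCD balancing-selection statistics), and
    inversion-eQTL and GWAS-signal enrichment analyses. A seeded synthetic
    data generator produces coalescent-style haplotype panels carrying
    inversions of configurable origin count and age, so every stage of the
    pipeline can be exercised and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    ape,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
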