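Package: urvburden
Title: Gene-Set Burden Analysis of Ultra-Rare Coding Variants in
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Collapsing burden analysis of ultra-rare coding variants
    (URVs) for case-control exome studies. Variants are qualified by
    internal minor allele count and external population frequencies
    (gnomAD, DiscovEHR), assigned to thirteen partially overlapping
    functional classes built from consequence annotations and missense
    constraint scores (PolyPhen-2, SIFT, MPC, MTR, constrained coding
    regions, paralog conservation), collapsed to per-sample gene-set
    burden scores, and tested for case-control enrichment with a
    covariate-adjusted logistic likelihood-ratio test followed by
    Benjamini-Hochberg adjustment over the full test grid. Includes a
    synthetic-cohort simulator with known spiked enrichments, the
    bias-control analyses (chromosome-X exclusion, controls-only
    capture-kit contrast, permutation subsampling, driver-gene
    sensitivity), and readers/writers for the tabular, GMT and VCF
    formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
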