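Package: msmapr
Title: Bulked-Segregant Mapping of a Recessive Male-Sterility Locus and
    Tassel Lipidome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidy pipeline for mapping a recessive nuclear male-sterility
    locus in maize from bulked-segregant RNA-seq allele counts and for
    quantifying the mutant tassel lipidome deficit. Implements the
    Euclidean-distance (ED) association statistic raised to the fifth power,
    per-chromosome LOESS smoothing with a median + 3 SD genome-wide
    threshold, candidate interval and gene calling from GFF3 annotation,
    recombinant-driven fine mapping under a recessive single-locus model,
    transposon-insertion characterization (target-site duplication and
    terminal inverted repeats), segregation and allelism chi-square tests,
    restriction-site genotyping, and a lipidomics arm (subclass Welch tests,
    PLS-DA variable importance in projection, chain-length/saturation
    profiles, hierarchical clustering). Seeded synthetic-data generators
    emulate an F2 population, finite-depth bulk sequencing, transposon
    insertion alleles, and a two-group lipidome so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
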