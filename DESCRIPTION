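Package: kscreen
Title: Genome-Wide Knockoff Screening of Common and Rare Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Window-based genome-wide screening for trait-associated loci in
    sequencing studies with guaranteed false discovery rate control via
    model-X knockoffs. Generates multiple exchangeable knockoff copies of an
    unphased genotype dosage matrix with a fast sequential conditional model,
    computes an ensemble association statistic per overlapping candidate
    window (single-variant score tests with an optional saddlepoint
    approximation for unbalanced case-control data, burden and dispersion
    (SKAT) tests, aggregation of ultra-rare variants, functional-annotation
    weighting, all combined by the Cauchy combination test), and applies a
    multiple-knockoff selection filter with knockoff Q-values. Includes a
    synthetic-data module that emulates LD-block-structured genotype panels
    and the phenotype-generation recipes used in the simulation designs.
License: MIT
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
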