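Package: tpcmap
Title: Function-Valued Thermal Performance Curves and QTL Mapping in
    Recombinant Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Treats behavioral thermal performance curves (TPCs) as
    function-valued traits and dissects them genetically in recombinant
    inbred line (RIL) panels. Provides a synthetic-data generator for
    advanced-intercross RIL genotypes and per-individual locomotion
    assays with planted QTL effects; locomotion metrics (changed-pixel
    locomotion index, displacement, proportion moving) with
    per-individual normalization and quality control; three-parameter
    logistic and Gaussian peak curve fitting with Wald confidence
    intervals; strain-by-metric trait tables and scaled principal
    component analysis; and QTL interval mapping built from first
    principles: hidden-Markov genotype probabilities, multiple
    imputation, Haley-Knott regression, permutation-based genome-wide
    thresholds, Bayes credible intervals, QTL heritability, conditional
    and two-dimensional scans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
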