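Package: ifnburden
Title: Rare-Variant Burden, Interferon Signatures, and Reporter-Assay
    Statistics for Monogenic Interferonopathy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative pipeline for candidate-gene studies of type I
    interferon-driven autoimmunity. Implements ultra-rare qualifying-variant
    filters and an exact binomial gene-burden carrier test against a
    population background; a combined variant-effect-predictor damage score
    by percentile normalization against a gene-specific reference background;
    six-gene qPCR and 24-probe NanoString interferon-signature scores with
    control-derived positivity thresholds; dual-luciferase reporter
    normalization with one-way ANOVA and Monte Carlo Dunnett comparisons
    against wild type; and box-statistic aggregation of per-model free-energy
    changes. A synthetic-data generator with planted ground truth exercises
    every stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
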