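Package: wheatms
Title: Discriminant Metabolite Profiling of LC-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric analysis of untargeted UPLC-TOF-MS metabolite
    feature tables for class discrimination, built around the workflow used
    to separate wheat market classes: replicate averaging, high-quality-ion
    filtering (class-wise presence and mean-intensity rules), Pareto
    scaling, PCA with Hotelling T-squared ellipses, multi-class OPLS-DA
    with predictive/orthogonal variance partitioning and 7-fold
    cross-validated Q2, S-plot construction with jack-knifed confidence
    intervals for biomarker ion selection, single-linkage dendrograms of
    predictive scores with compactness and distinctness metrics, Fisher
    exact point probabilities of confusion tables, and ESI+ adduct-mass
    annotation against an offline compound database with Lipid Maps
    category and polarity assignment. A synthetic feature-table generator
    with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
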