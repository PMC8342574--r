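Package: twinbiome
Title: Twin-Design Heritability Analysis of Microbiome Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the heritability of microbial taxa from classical
    twin designs. Provides maximum-likelihood ACE/AE/CE/E variance-component
    models on the covariance structure of monozygotic and dizygotic twin
    pairs, profile-likelihood confidence intervals, likelihood-ratio model
    comparison, arcsine-square-root transformation of taxa proportions,
    prevalence/abundance taxa filtering, read-depth screening, cohort
    descriptive statistics, a synthetic twin-cohort simulator for power and
    calibration studies, and an end-to-end analysis pipeline producing
    per-taxon, per-stratum heritability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
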