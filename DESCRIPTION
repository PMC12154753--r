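Package: spiroref
Title: Spirometric Reference Equations via GAMLSS-Style Location-Scale-Shape Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, evaluating and validating spirometric
    reference equations for adult populations. Implements Z-score, centile
    and lower-limit-of-normal machinery for the Box-Cox Cole-Green (BCCG)
    and Box-Cox power-exponential (BCPE) distributions, ships the published
    Iraqi Spirometric Equations (ISE) as a packaged equation set, refits
    reference equations from cohort data by penalised backfitting over
    location, scale and shape parameters with Schwarz Bayesian criterion
    model selection and worm-plot diagnostics, and provides phase-two
    validation statistics (Z-score summaries, the GLI +/-0.5 suitability
    rule, equation-set comparison, Mann-Whitney U phase tests). A synthetic
    cohort generator reproduces the demographic structure of the derivation
    study so the full pipeline is testable without the original data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    mgcv
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
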