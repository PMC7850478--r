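Package: mmlineage
Title: Single-Cell Lineage Statistics for Mammalian Mother-Machine Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-cell lineage time-lapse observations from
    mother-machine microfluidic devices, motivated by long-term tracking of
    mouse lymphocytic leukemia (L1210) cells. Provides an event-table data
    model for division/death records per growth channel; a mixed
    shifted-exponential generation-time model with a two-stage survival-curve
    fit and a consistent EM maximum-likelihood fit; population division- and
    death-rate estimators; mother-daughter generation-time correlation,
    autocorrelation, resampling and intra-lineage correlation statistics;
    Grassberger-Procaccia correlation-dimension analysis of generation-time
    series; growth-state-stratified drug-survival analysis; and a calibrated
    synthetic lineage generator with a lineage-persistent plus AR(1) Gaussian
    copula that reproduces the two-timescale heritability of generation times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
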