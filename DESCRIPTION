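Package: laef
Title: Automated Left Atrial Function Analysis from Time-Resolved Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies left atrial (LA) function from time-resolved (CINE)
    cardiac MRI segmentations. Converts 4D binary LA masks into calibrated
    volume-time curves, automatically detects the fiducial points of the
    atrial cycle (maximum, minimum, pre-atrial-contraction and diastasis
    volumes), computes total, active and passive LA emptying fractions with
    body-surface-area indexed volumes (Mosteller), derives clinical atrial
    fibrillation classifications (AF Burden score, CHA2DS2-VASc stroke-risk
    group, EHRA class), and reproduces the cohort statistics layer:
    normality-routed group comparisons with Bonferroni post-hoc correction,
    Fisher exact tests, and forward-stepwise multivariable linear regression
    with forced covariates. A synthetic-data module simulates biphasic
    volume-time curves (sinus, AF-mode, extrasystole-corrupted) and cohort
    tables with known generative coefficients so that every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
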