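Package: abpmonitor
Title: Athlete Biological Passport Monitoring with Training-Load Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal hematological monitoring of endurance
    athletes in the spirit of the Athlete Biological Passport (ABP):
    marker scoring (OFF-score) and analyzer replicate quality control,
    adaptive Bayesian individual reference limits with atypical-finding
    flags, carbon-monoxide rebreathing total hemoglobin mass and
    blood/plasma volume computation, power-based training-load
    quantification (normalized power, TSS, acute and chronic load
    windows, seasonal and high/low periods, hypoxic dose), mixed-model
    statistics linking training load to blood markers, and a seeded
    synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    nlme,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    jsonlite,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
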