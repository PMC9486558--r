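Package: chronotox
Title: Treatment-Time and Circadian-Genotype Modelling of Radiotherapy Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chronoradiotherapy analysis of breast radiotherapy
    cohorts: conversion of per-fraction treatment times to apparent solar
    time, biologically effective dose (BED) computation, toxicity endpoint
    dichotomization and cohort exclusion rules, AIC-based scanning for the
    peak-toxicity time of day, circadian-SNP by treatment-time interaction
    models, Hardy-Weinberg composite genotype risk scores, and
    genotype-conditional optimal-treatment-time prediction. Includes a
    multi-site synthetic cohort generator emulating the structure of a
    European breast radiotherapy cohort so that every pipeline stage can be
    exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    lme4,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    vcfR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
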