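Package: efastress
Title: Stress-Test Analysis for Extracellular Flux Plate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of plate-based extracellular flux (oxygen consumption
    and extracellular acidification) stress tests. Implements blank
    correction, per-cell normalization and phase-representative rate
    extraction for 96-well runs; the six mitochondrial stress-test
    respiration parameters with paired arms run with and without ATP
    synthase (complex V) inhibition and the resulting percent
    underestimation of maximal respiration and spare respiratory capacity;
    ECAR-to-proton-efflux-rate conversion with buffering factor and CO2
    contribution factor, and the four glycolytic parameters; mitochondrial,
    glycolytic and total ATP production rates; replicate aggregation with
    Tukey's-fences outlier handling, ANOVA/Dunnett/Tukey/Levene statistics,
    Cohen's d and dose-response slope tests; and a seeded synthetic
    plate-run generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    withr,
    jsonlite,
    yaml,
    multcomp,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
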