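Package: degronKinetics
Title: Quantitative Analysis of Degron-Controlled CRISPR Repressor Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis framework for degron-tunable CRISPR repression systems
    measured by flow cytometry. Provides gating and median-fluorescence
    summarisation of single-cell event data, degron characterisation metrics
    (leakiness, efficiency, dynamic range), ODE-based estimation of repressor
    and target kinetics (half-times, Hill repression parameters, target
    degradation rate, repression/derepression delays by mean-absolute-error
    minimisation), four-parameter Hill dose-response fitting for titrated
    transcription factors, and a critical-bandwidth (Hall-York) test that
    classifies repression as analog (unimodal) or digital (bimodal) at the
    single-cell level. A seeded synthetic-data generator emulates the
    statistical structure of the assays so the whole pipeline is testable
    without raw cytometry files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
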