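Package: pmgflow
Title: Pollen-Mediated Gene Flow Analysis with Double Exponential Decay
    Dispersal Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying pollen-mediated gene flow (PMGF) from
    concentric (Nelder wheel) field experiments in which a central block of
    herbicide-resistant pollen donors is surrounded by susceptible receptor
    stations along eight compass arms. Provides descriptive gene-flow and
    flowering-synchrony statistics, wind-rose summaries (sector frequency,
    mean speed, wind run) and PMGF-wind correlations, a double exponential
    decay binomial logit dispersal model fitted by maximum likelihood with
    AIC model selection over a configurable candidate family, estimation of
    the distances at which gene flow falls by 50% and 90% (O50/O90) with
    parametric-bootstrap confidence intervals, Pearson chi-squared goodness
    of fit for grouped binomial data, binomial detection-power and minimum
    sample-size calculations, and a seeded synthetic-data generator that
    emulates the statistical structure of such field studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
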