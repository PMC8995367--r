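Package: metaconf
Title: Confidence Forced-Choice Analysis of Visual Metacognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-task confidence forced-choice
    experiments on visual contrast discrimination. Builds chosen and
    unsorted confidence sets from trial-level data, fits cumulative
    Gaussian psychometric functions by penalized maximum likelihood,
    quantifies metacognitive efficiency with the Confidence Modulation
    Index (CMI), fits an exponential response-time model separating
    stimulus-intensity and confidence effects, and reproduces the study
    statistics (mixed ANOVA, Levene-gated t-tests, bootstrap confidence
    intervals, partial correlations with an executive-function
    composite). Includes a generative signal-detection-theory observer
    that simulates complete sessions and cohorts for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    car,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
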