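Package: ineqshift
Title: Hypothetical Interventions on Inequalities in Antenatal Care Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates inequalities in gestational age at antenatal care
    initiation across individual and socioeconomic groups, and the reduction
    of those inequalities under a hypothetical intervention in which every
    participant recognises the pregnancy within 6 gestational weeks.
    Implements g-computation with a linear outcome model, multiple imputation
    by chained equations with Rubin pooling, percentile-bootstrap confidence
    intervals combined with multiple imputation, positivity diagnostics via
    propensity scores, and a synthetic cohort generator calibrated to
    published cohort marginals for fully reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
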