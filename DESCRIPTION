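Package: samplingvalue
Title: Marginal Value of Citizen-Science Checklists for Biodiversity Trend
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores citizen-science bird checklists by their statistical
    leverage on many species' population-trend models and forecasts where
    future sampling would be most informative. Fits per-species binomial
    presence/absence trend models with a list-length offset, computes the
    one-step dfBeta influence of every checklist on each species' trend
    coefficient, sums absolute influences into a per-checklist marginal
    value, relates that value to dynamic per-grid-cell sampling-history
    covariates, and predicts daily maps of expected marginal value at
    several spatial grains. Includes a synthetic checklist-world simulator
    with known trends, county structure and hotspot-biased effort so the
    whole pipeline can be validated without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
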