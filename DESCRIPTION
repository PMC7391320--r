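Package: reeftrends
Title: Trend-Based Detection of Trophic Cascades in Long-Term Reef Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing trophic forcing in hierarchical reef
    monitoring time series. Aggregates transect-level survey records to
    standardized annual density series per trophic group (predators,
    herbivores, algae) at each location, fits per-series linear and
    AR(1)-correlated trend models, computes adjacent-group Pearson
    correlations with Fisher-z inverse-variance weights, applies an
    alternating-trend trophic-cascade classification rule, and relates
    trends and cascade prevalence to latitude and exploitation status via
    weighted regression and binomial logit models with backward stepwise
    selection. Includes a tri-trophic synthetic monitoring-data generator
    with latent AR(1) year effects and site/transect variance components
    for calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
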