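Package: phenospace
Title: Background-Climate Controls on the Spatial Variance of Spring Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how long-term background climate shapes the
    spatial variance of spring leaf unfolding (LU) and its heat requirement
    across site networks. Computes thermal-time phenometrics (growing-degree-day
    accumulation, heat requirement at leaf unfolding, chilling days), long-term
    climate-normal predictors (seasonal-window temperature, radiation,
    precipitation and soil moisture, day length, and a Priestley-Taylor
    evapotranspiration-ratio aridity index), and a four-step statistical engine:
    pairwise collinearity screening, elastic-net predictor selection,
    variance-inflation-factor stepwise reduction, and spatially correlated
    generalized least squares with AIC structure selection, summarised as an
    R-squared decomposition of predictor relative importance with bootstrap
    confidence intervals. Includes a synthetic site-network generator with a
    known adaptive thermal-time mechanism for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
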