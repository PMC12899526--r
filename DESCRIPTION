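Package: ssbtax
Title: Health and Cost Impacts of Sugar-Sweetened Beverage Taxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the population health and healthcare cost impacts of an
    excise tax on sugar-sweetened beverages with a proportional multistate life
    table model. A tax scenario is translated into price changes, beverage
    demand responses through own- and cross-price elasticities, and daily
    energy intake changes per population stratum; sustained energy changes are
    converted into body-weight and body-mass-index trajectories with the Hall
    dynamic energy-balance model; BMI shifts are propagated to chronic disease
    incidence through potential impact fractions (with diabetes acting as both
    an outcome and a mediator for cardiovascular disease); and a closed-cohort
    multistate life table accumulates quality-adjusted life years, healthcare
    costs, and disease cases averted under configurable discounting. Parametric
    uncertainty is propagated by Monte Carlo simulation, and a synthetic-data
    generator produces internally consistent input bundles for testing and
    method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
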