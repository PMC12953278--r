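Package: tempmort
Title: Distributed Lag Non-Linear Modelling and Projection of
    Temperature-Attributable Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating temperature-mortality associations from
    daily all-cause death counts and mean temperatures with distributed lag
    non-linear models (quasi-Poisson time-series regression on a natural
    cubic spline cross-basis), reducing the fitted surface to an overall
    cumulative relative-risk curve centred at a fixed minimum-mortality
    temperature, computing heat- and cold-attributable deaths and fractions
    with Monte-Carlo confidence intervals, and projecting the burden onto
    multi-model climate scenario ensembles by decade under adaptation and
    population-growth assumptions. Includes a synthetic-data generator that
    emulates censored regional mortality series and pseudo climate-model
    trajectories so the whole pipeline can be exercised without restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
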