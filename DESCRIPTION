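Package: aqews
Title: Air-Quality Early-Warning System: Decomposition-Ensemble Forecasting and Fuzzy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An air-quality early-warning toolkit for daily pollutant
    concentration series (PM2.5, PM10, NO2, SO2, CO, O3). Forecasting
    follows the decomposition-and-integration strategy: series are split
    into intrinsic mode functions by improved complete ensemble empirical
    mode decomposition with adaptive noise (ICEEMDAN), each mode is
    predicted one step ahead by an extreme learning machine whose hidden
    parameters are tuned by the whale optimization algorithm (WOA), and
    the mode forecasts are summed. Forecast accuracy is reported as MAE,
    RMSE, MAPE and Theil's inequality coefficient, with Diebold-Mariano
    comparison of competing models. Predicted concentrations are then
    graded into five air-quality levels by fuzzy comprehensive evaluation
    with halved-trapezoidal memberships and multi-scale factor weights,
    and mapped to early-warning handbook advice. A synthetic-data
    generator emulating urban pollutant statistics makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
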