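Package: demandcast
Title: Forecasting Daily Emergency-Department Demand with Rolling-Origin
    Backtests, Streaming Hyperparameter Selection and Convex Stacking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified framework for forecasting daily emergency-department
    attendance 1, 3 or 7 days ahead. Provides a synthetic attendance/covariate
    generator with weekly, annual, holiday, event, weather and flu-search
    structure; lagged-covariate model matrices with a strict no-leakage
    contract; a uniform adapter over nine time-series and machine-learning
    forecasters; rolling-origin temporal cross-validation with one-day test
    sets; batch (five selection rules) and online (periodic refit)
    hyperparameter-selection policies; a convex-combination least-squares
    stacker; and MAE/MAPE scoreboards, permutation variable importance and
    exploratory diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    ranger,
    xgboost,
    caret,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
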