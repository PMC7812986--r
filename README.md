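# demandcast

Forecasting daily emergency-department (ED) demand 1, 3 or 7 days ahead,
and comparing and combining heterogeneous forecasters fairly under a
rolling-origin backtesting discipline.

EDs plan staffing against tomorrow's (or next week's) patient arrivals.
Daily attendance counts have strong, exploitable structure — Monday peaks
and weekend troughs, winter surges, slow trends, holiday dips, one-off
event spikes (a local carnival, Christmas) — on top of overdispersed count
noise. This package implements a complete workflow for that problem:

* **Synthetic data** — `generate_demand()` simulates attendance series and
  covariate calendars (holidays, weather, flu-search volume) with that
  structure, calibrated to published mean demand levels near 208 and 106
  patients/day, so every downstream stage is testable without access to
  hospital records.
* **Features** — `build_model_matrix()` builds lagged-covariate rows
  (previous-day demand, same day last week, previous-week average,
  calendar/weather/search covariates) under a strict no-leakage contract:
  every lag is a function only of counts dated at or before the forecast
  origin `target − horizon`.
* **Learners** — one fit/predict adapter over nine forecasters: seasonal
  ARIMA, exponential smoothing (ETS), STL-based, structural state-space,
  and five machine-learning learners (lm, elastic net, random forest,
  gradient boosting, k-NN), with declared default grids.
* **Temporal CV** — `make_split_plan()` / `run_backtest()`: fixed-width
  rolling windows, one-day test sets, origin advancing a day per fold.
* **Tuning** — `run_batch_method()` (five selection rules over streaming
  validation errors: previous day, past *n* days, exponential moving
  average, whole-period average, resample-average with complexity
  tie-breaks) and `run_online_method()` (hyperparameters and fits frozen
  over configurable refit periods).
* **Stacking** — `fit_stack()` solves the convex-constrained least-squares
  program min ‖y − Pw‖² s.t. w ≥ 0, Σw = 1 exactly (simplex face
  enumeration), so the ensemble forecast always lies within the range of
  its inputs; `fit_stack_tuned()` adds a forward-validated ridge penalty.
* **Evaluation** — `mae()`, `mape()`, `scoreboard()`,
  `permutation_importance()`, `demand_diagnostics()` (STL decomposition,
  weekday/monthly profiles, autocorrelation).

## Worked example

```r
library(demandcast)

cfg <- st_marys_config(n_days = 400L, seed = 42L)   # ~208 patients/day
gen <- generate_demand(cfg)
mean(gen$series$count)                              # 208.4

# backtest three learners over the last 14 days, horizon 1
plan <- make_split_plan(400, 14, 1)                 # train_length 386, 14 folds
logs <- list()
for (nm in c("stlm", "lm", "glmnet")) {
  spec <- learner_spec(nm, grid = if (nm == "glmnet")
    list(list(mixture = 0.5, lambda = 1)) else list(list()))
  logs[[nm]] <- run_backtest(gen$series, gen$calendar, spec, plan, seed = 1L)
}
scoreboard(logs)
#>   configuration learner horizon      mae     mape n_records n_skipped
#> 1        glmnet  glmnet       1 13.47217 6.095944        14         0
#> 2            lm      lm       1 14.11024 6.371025        14         0
#> 3          stlm    stlm       1 14.38725 6.416571        14         0

tab <- stacking_table(logs)
fit_stack(tab$predictions, tab$actuals)
#>   stlm     lm glmnet
#>      0      0      1
```

Reading the output: each learner was refitted 14 times on a 386-day
rolling window and scored one day ahead; the elastic net's mean absolute
error is 13.5 patients (6.1% of demand). On this short fitting window the
convex stacker concentrates all weight on the single best learner — its
zero-weight vertices are feasible solutions, so in-sample it can never do
worse than the best input.

The batch and online tuning policies and the full pipeline follow the same
pattern; see `?run_batch_method`, `?run_online_method`, `?run_pipeline`,
and the methods vignette in `vignettes/demand-forecasting-methods.Rmd`.
A thin command-line interface over these functions ships in
`inst/cli/demandcast.R` (subcommands `simulate`, `features`, `backtest`,
`tune`, `stack`, `report`, `importance`, `run`).

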