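#' Lay out rolling-origin train/test splits
#'
#' Each fold forecasts a single future day: a training window of exactly
#' `train_length` days ends at the fold's origin, and the target lies
#' `horizon` days past the origin. Consecutive folds advance the origin by
#' one day (a rolling, fixed-width window — the origin moves forward so all
#' training sets have the same number of days). The last fold's target is
#' the final day of the series, so the `test_length` folds cover the last
#' `test_length` days.
#'
#' @param n_total Total number of days available.
#' @param test_length Number of held-out test days (= number of folds).
#' @param horizon Forecast horizon in days (1, 3 or 7).
#' @param train_length Fixed training-window width in days. Defaults to
#'   `n_total - test_length`, capped at the maximum feasible width when a
#'   multi-day horizon would otherwise push the first window before day 1.
#' @return A `split_plan`: data frame with columns `fold`, `train_start`,
#'   `origin`, `target` (1-based day indices) and attributes `horizon`,
#'   `train_length`, `test_length`.
#' @export
make_split_plan <- function(n_total, test_length, horizon,
                            train_length = NULL) {
  n_total <- as.integer(n_total); test_length <- as.integer(test_length)
  horizon <- as.integer(horizon)
  if (!horizon %in% c(1L, 3L, 7L))
    stop_demandcast("unsupported horizon %d: must be one of 1, 3, 7",
                    horizon, class = "demandcast_horizon_error")
  if (test_length < 1L || test_length > n_total)
    stop_demandcast("test_length must be in [1, n_total]",
                    class = "demandcast_sizing_error")
  max_train <- n_total - test_length - horizon + 1L
  if (is.null(train_length))
    train_length <- min(n_total - test_length, max_train)
  train_length <- as.integer(train_length)
  if (train_length < 1L || train_length > max_train)
    stop_demandcast(
      "infeasible split geometry: maximum feasible train_length is %d (got %d)",
      max_train, train_length, class = "demandcast_sizing_error")
  target <- seq.int(n_total - test_length + 1L, n_total)
  origin <- target - horizon
  plan <- data.frame(fold = seq_along(target),
                     train_start = origin - train_length + 1L,
                     origin = origin, target = target)
  structure(plan, horizon = horizon, train_length = train_length,
            test_length = test_length,
            class = c("split_plan", "data.frame"))
}

new_forecast_log <- function() {
  data.frame(target_date = as.Date(character()), horizon = integer(),
             learner = character(), hyperparam_id = character(),
             prediction = numeric(), actual = numeric(),
             absolute_error = numeric(), status = character(),
             reason = character())
}

forecast_log_row <- function(target_date, horizon, learner, hp_id,
                             prediction, actual, status = "ok",
                             reason = NA_character_) {
  data.frame(target_date = target_date, horizon = horizon,
             learner = learner, hyperparam_id = hp_id,
             prediction = prediction, actual = actual,
             absolute_error = abs(prediction - actual),
             status = status, reason = reason)
}

# Fit one (fold, setting) and predict the fold's single target.
fold_predict <- function(spec, hp, counts, rows_all, fold, horizon, seed) {
  # ML training rows: targets inside the training window (their own lags
  # reach at most 7 days before the window start, all dated <= origin)
  train <- list(
    counts = counts[fold$train_start:fold$origin],
    rows = if (spec$family == "ml")
      rows_in_targets(rows_all, fold$train_start, fold$origin) else NULL)
  fitted <- fit_learner(spec, hp, train, seed = seed)
  if (inherits(fitted, "fit_failure")) return(fitted)
  if (spec$family == "time_series") {
    predict_learner(fitted, list(h = horizon))
  } else {
    row <- rows_in_targets(rows_all, fold$target, fold$target)
    if (!nrow(row))
      return(structure(list(spec = spec,
                            reason = "no feature row for target"),
                       class = "fit_failure"))
    predict_learner(fitted, row)
  }
}

# model-matrix rows whose target index lies in [from, to]
rows_in_targets <- function(rows_all, from, to) {
  idx <- attr(rows_all, "target_index")
  keep <- idx >= from & idx <= to
  out <- rows_all[keep, , drop = FALSE]
  attr(out, "feature_cols") <- attr(rows_all, "feature_cols")
  attr(out, "horizon") <- attr(rows_all, "horizon")
  out
}

# Attach 1-based target day indices to a model matrix for fast fold slicing.
index_model_matrix <- function(mm, series) {
  attr(mm, "target_index") <-
    as.integer(mm$target_date - series$date[1]) + 1L
  mm
}

#' Run a rolling-origin backtest
#'
#' For every fold of the plan and every hyperparameter setting of the
#' learner's grid, fits on the fold's fixed-width training window and
#' records the single-target prediction against the actual. Forecast errors
#' are blind to held-out data: no feature or fit sees counts dated after the
#' fold's origin. Fit failures are logged with status `"skipped"` and the
#' failure reason, never raised.
#'
#' @param series A `demand_series`.
#' @param calendar Matching `covariate_calendar`.
#' @param spec A [learner_spec()].
#' @param plan A [make_split_plan()] for the same series.
#' @param seed Root seed; each (fold, setting) gets a derived child seed.
#' @param grid Optional grid override (defaults to `spec$grid`).
#' @return A `forecast_log` data frame: one record per
#'   (target_date, learner, hyperparam_id).
#' @export
run_backtest <- function(series, calendar, spec, plan, seed = 1L,
                         grid = spec$grid) {
  validate_demand_series(series)
  horizon <- attr(plan, "horizon")
  counts <- series$count
  rows_all <- if (spec$family == "ml")
    index_model_matrix(build_model_matrix(series, calendar, horizon), series)
  else NULL
  if (is.null(names(grid))) names(grid) <- sprintf("hp%02d", seq_along(grid))
  logs <- vector("list", nrow(plan) * length(grid))
  k <- 0L
  for (f in seq_len(nrow(plan))) {
    fold <- plan[f, ]
    target_date <- series$date[1] + (fold$target - 1L)
    actual <- counts[fold$target]
    for (j in seq_along(grid)) {
      k <- k + 1L
      pred <- fold_predict(spec, grid[[j]], counts, rows_all, fold, horizon,
                           seed = child_seed(seed, f, j))
      logs[[k]] <- if (inherits(pred, "fit_failure")) {
        forecast_log_row(target_date, horizon, spec$name, names(grid)[j],
                         NA_real_, actual, status = "skipped",
                         reason = pred$reason)
      } else {
        forecast_log_row(target_date, horizon, spec$name, names(grid)[j],
                         pred, actual)
      }
    }
  }
  out <- do.call(rbind, logs)
  class(out) <- c("forecast_log", "data.frame")
  out
}
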