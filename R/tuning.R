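#' Hyperparameter-selection rules for streaming backtests
#'
#' A selection rule turns a panel of past validation errors into a choice
#' of hyperparameter setting for the next forecast day. The five rules pick
#' the setting minimising the error
#' \enumerate{
#'   \item on the previous day (`previous_day`),
#'   \item on the past `n` days (`past_n_days`),
#'   \item over the whole validation period using an exponential moving
#'     average (`ema`),
#'   \item averaged over the whole validation period
#'     (`validation_average`),
#'   \item averaged over all validation resamples with ties broken toward
#'     the least complex setting (`default_resample`).
#' }
#'
#' @param kind One of `"previous_day"`, `"past_n_days"`, `"ema"`,
#'   `"validation_average"`, `"default_resample"`.
#' @param n Window length for `past_n_days` (default 7, a declared
#'   convention).
#' @param alpha Smoothing weight in `(0, 1]` for `ema` (default 0.1, a
#'   declared convention); `alpha = 1` reproduces `previous_day`.
#' @return A `selection_rule`.
#' @export
selection_rule <- function(kind, n = 7L, alpha = 0.1) {
  kind <- match.arg(kind, selection_rule_kinds())
  n <- as.integer(n)
  if (n < 1L)
    stop_demandcast("selection rule: n must be >= 1",
                    class = "demandcast_config_error")
  if (!(alpha > 0 && alpha <= 1))
    stop_demandcast("selection rule: alpha must be in (0, 1]",
                    class = "demandcast_config_error")
  structure(list(kind = kind, n = n, alpha = alpha),
            class = "selection_rule")
}

#' @rdname selection_rule
#' @export
selection_rule_kinds <- function() {
  c("previous_day", "past_n_days", "ema", "validation_average",
    "default_resample")
}

#' Assemble a validation-error panel from a forecast log
#'
#' Restricts a [run_backtest()] log for one learner to its successful
#' records and reshapes them into a per-(setting, date) absolute-error
#' panel, the substrate of [select_hyperparams()].
#'
#' @param log A `forecast_log` for a single learner.
#' @return A `validation_panel`: data frame with `date`, `hyperparam_id`,
#'   `absolute_error`, plus attributes `learner` and `complexity` (named
#'   tie-break scores per setting).
#' @export
validation_panel <- function(log) {
  ok <- log[log$status == "ok", , drop = FALSE]
  if (!nrow(ok))
    stop_demandcast("empty panel: log has no successful records",
                    class = "demandcast_selection_error")
  if (length(unique(ok$learner)) > 1L)
    stop_demandcast("panel must come from a single learner",
                    class = "demandcast_selection_error")
  panel <- data.frame(date = ok$target_date,
                      hyperparam_id = ok$hyperparam_id,
                      absolute_error = ok$absolute_error)
  panel <- panel[order(panel$date, panel$hyperparam_id), , drop = FALSE]
  rownames(panel) <- NULL
  structure(panel, learner = ok$learner[1],
            class = c("validation_panel", "data.frame"))
}

panel_append <- function(panel, date, hyperparam_id, absolute_error) {
  add <- data.frame(date = date, hyperparam_id = hyperparam_id,
                    absolute_error = absolute_error)
  out <- rbind(as.data.frame(panel), add)
  out <- out[order(out$date, out$hyperparam_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, learner = attr(panel, "learner"),
            class = c("validation_panel", "data.frame"))
}

# Rule criterion over one setting's chronologically ordered error history.
rule_criterion <- function(errors, rule) {
  if (!length(errors)) return(Inf)
  switch(rule$kind,
    previous_day = errors[length(errors)],
    past_n_days = mean(tail(errors, rule$n)),
    ema = {
      e <- errors[1]
      if (length(errors) > 1)
        for (x in errors[-1]) e <- rule$alpha * x + (1 - rule$alpha) * e
      e
    },
    validation_average = mean(errors),
    default_resample = mean(errors))
}

#' Select hyperparameters from past validation errors
#'
#' Computes the rule's criterion for every setting from its errors dated
#' strictly before `as_of` and returns the minimising setting. Ties break
#' deterministically: lowest criterion, then (for `default_resample`) the
#' least complex setting, then the lowest `hyperparam_id` in the declared
#' grid order. Settings with no errors before `as_of` are never selected
#' unless no setting has any.
#'
#' @param panel A [validation_panel()].
#' @param rule A [selection_rule()] (or a rule kind string).
#' @param as_of The prediction date; only errors dated `< as_of` are used.
#' @param complexity Optional named numeric tie-break scores per setting
#'   (lower = less complex), used by `default_resample`.
#' @return The selected `hyperparam_id` (character scalar).
#' @export
select_hyperparams <- function(panel, rule, as_of, complexity = NULL) {
  if (is.character(rule)) rule <- selection_rule(rule)
  use <- panel[panel$date < as.Date(as_of), , drop = FALSE]
  ids <- sort(unique(panel$hyperparam_id))
  if (!nrow(use))
    stop_demandcast("no errors available before %s", format(as_of),
                    class = "demandcast_selection_error")
  crit <- vapply(ids, function(id) {
    e <- use$absolute_error[use$hyperparam_id == id]
    rule_criterion(e, rule)
  }, 0)
  if (all(!is.finite(crit)))
    stop_demandcast("no setting has errors before %s", format(as_of),
                    class = "demandcast_selection_error")
  comp <- if (rule$kind == "default_resample" && !is.null(complexity))
    complexity[ids] else rep(0, length(ids))
  comp[is.na(comp)] <- 0
  ord <- order(crit, comp, ids)
  ids[ord[1]]
}

grid_complexity <- function(spec) {
  vapply(spec$grid, function(hp) complexity_score(spec$name, hp), 0)
}

#' Run the batch hyperparameter-selection method
#'
#' The batch method refits all settings of a learner every day. A full-grid
#' rolling-origin backtest covers the validation block and the test block;
#' then, for each test day and each rule, the setting minimising the rule's
#' criterion over all errors dated strictly before that day is selected and
#' its (already computed, daily-refit) forecast becomes the day's batch
#' forecast. The error panel rolls forward: realized test-day errors join
#' the panel for later selections.
#'
#' @param series,calendar The demand series and covariate calendar.
#' @param spec A [learner_spec()].
#' @param rules One or more [selection_rule()]s (or kind strings); all
#'   rules share the same underlying backtest.
#' @param horizon Forecast horizon (1, 3 or 7).
#' @param train_length,val_length,test_length Block lengths in days: the
#'   trailing `test_length` days are the test block, preceded by the
#'   `val_length`-day validation block; every fit uses a `train_length`-day
#'   rolling window.
#' @param seed Root seed.
#' @return A list with `forecasts` (named list per rule of one-record-per-
#'   test-day `forecast_log`s), `selections` (data frame `date`, `rule`,
#'   `hyperparam_id`), and `log` (the full-grid backtest log).
#' @export
run_batch_method <- function(series, calendar, spec,
                             rules = selection_rule_kinds(),
                             horizon = 1L, train_length, val_length,
                             test_length, seed = 1L) {
  rules <- normalize_rules(rules)
  n <- nrow(series)
  if (train_length + val_length + test_length + horizon - 1L > n)
    stop_demandcast(
      "infeasible geometry: train %d + validation %d + test %d + horizon %d - 1 exceeds %d days",
      train_length, val_length, test_length, horizon, n,
      class = "demandcast_sizing_error")
  plan <- make_split_plan(n, val_length + test_length, horizon, train_length)
  log <- run_backtest(series, calendar, spec, plan, seed = seed)
  test_dates <- series$date[seq.int(n - test_length + 1L, n)]
  panel <- validation_panel(log)
  comp <- grid_complexity(spec)
  selections <- list(); forecasts <- list()
  for (rn in names(rules)) {
    sel <- vapply(as.character(test_dates), function(d)
      select_hyperparams(panel, rules[[rn]], as.Date(d), complexity = comp),
      "")
    selections[[rn]] <- data.frame(date = test_dates, rule = rn,
                                   hyperparam_id = unname(sel))
    picked <- merge(selections[[rn]][, c("date", "hyperparam_id")],
                    as.data.frame(log),
                    by.x = c("date", "hyperparam_id"),
                    by.y = c("target_date", "hyperparam_id"))
    picked <- picked[order(picked$date), , drop = FALSE]
    fl <- forecast_log_row(picked$date, horizon, spec$name,
                           picked$hyperparam_id, picked$prediction,
                           picked$actual, status = picked$status,
                           reason = picked$reason)
    class(fl) <- c("forecast_log", "data.frame")
    forecasts[[rn]] <- fl
  }
  list(forecasts = forecasts,
       selections = do.call(rbind, c(selections, make.row.names = FALSE)),
       log = log)
}

normalize_rules <- function(rules) {
  if (inherits(rules, "selection_rule")) rules <- list(rules)
  rules <- lapply(rules, function(r)
    if (is.character(r)) selection_rule(r) else r)
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    names(rules) <- vapply(rules, function(r) r$kind, "")
  rules
}

#' Run the online hyperparameter-selection method
#'
#' Trades accuracy for compute by keeping the selected setting and the
#' fitted model fixed over refit periods. The test block is partitioned
#' into consecutive blocks of `period` days. At each block boundary the
#' rule selects a setting from all errors dated strictly before the
#' boundary (validation errors plus realized errors of previously chosen
#' settings), and the learner is refitted once on the rolling window ending
#' at the boundary origin. Within a block, ML learners apply the frozen fit
#' to each day's fresh feature row; time-series learners forecast the
#' growing horizon from the boundary fit. Selection events therefore number
#' `ceiling(test_length / period)`.
#'
#' @inheritParams run_batch_method
#' @param period Refit period in days (e.g. 1, 7, 30, 60, 365, 730).
#' @param rule The [selection_rule()] applied at block boundaries (default
#'   `validation_average`; with `period = 1` and rule `previous_day` the
#'   selection sequence matches the batch method's under the same panel).
#' @param val_log Optional precomputed full-grid validation `forecast_log`
#'   for this learner over the validation block (e.g. sliced from a
#'   [run_batch_method()] log); when supplied, the validation backtest is
#'   not recomputed — useful when running several refit periods.
#' @return A list with `forecast` (a `forecast_log`, one record per test
#'   day), `selections` (data frame `date`, `hyperparam_id`, one row per
#'   block), and `panel` (the final rolled-forward panel).
#' @export
run_online_method <- function(series, calendar, spec, period,
                              rule = selection_rule("validation_average"),
                              horizon = 1L, train_length, val_length,
                              test_length, seed = 1L, val_log = NULL) {
  if (is.character(rule)) rule <- selection_rule(rule)
  period <- as.integer(period)
  if (period < 1L)
    stop_demandcast("period must be >= 1", class = "demandcast_config_error")
  n <- nrow(series)
  if (train_length + val_length + test_length + horizon - 1L > n)
    stop_demandcast(
      "infeasible geometry: train %d + validation %d + test %d + horizon %d - 1 exceeds %d days",
      train_length, val_length, test_length, horizon, n,
      class = "demandcast_sizing_error")
  train_len <- as.integer(train_length)
  if (is.null(val_log)) {
    val_plan <- make_split_plan(n - test_length, val_length, horizon,
                                train_len)
    val_log <- run_backtest(series[seq_len(n - test_length), , drop = FALSE],
                            calendar, spec, val_plan, seed = seed)
  } else {
    val_log <- val_log[val_log$target_date <=
                         series$date[n - test_length], , drop = FALSE]
  }
  panel <- validation_panel(val_log)
  comp <- grid_complexity(spec)
  counts <- series$count
  rows_all <- if (spec$family == "ml")
    index_model_matrix(build_model_matrix(series, calendar, horizon), series)
  else NULL
  test_idx <- seq.int(n - test_length + 1L, n)
  block_starts <- test_idx[seq.int(1L, test_length, by = period)]
  logs <- list(); selections <- list()
  for (b in seq_along(block_starts)) {
    start <- block_starts[b]
    block <- start:min(start + period - 1L, n)
    boundary_date <- series$date[start]
    hp_id <- select_hyperparams(panel, rule, boundary_date,
                                complexity = comp)
    selections[[b]] <- data.frame(date = boundary_date,
                                  hyperparam_id = hp_id)
    origin <- start - horizon
    train <- list(
      counts = counts[(origin - train_len + 1L):origin],
      rows = if (spec$family == "ml")
        rows_in_targets(rows_all, origin - train_len + 1L, origin)
      else NULL)
    fitted <- fit_learner(spec, spec$grid[[hp_id]], train,
                          seed = child_seed(seed, 1000L + b))
    for (t in block) {
      target_date <- series$date[t]
      actual <- counts[t]
      rec <- if (inherits(fitted, "fit_failure")) {
        forecast_log_row(target_date, horizon, spec$name, hp_id, NA_real_,
                         actual, status = "skipped", reason = fitted$reason)
      } else {
        pred <- if (spec$family == "time_series") {
          predict_learner(fitted, list(h = t - origin))
        } else {
          row <- rows_in_targets(rows_all, t, t)
          predict_learner(fitted, row)
        }
        forecast_log_row(target_date, horizon, spec$name, hp_id, pred, actual)
      }
      logs[[length(logs) + 1L]] <- rec
      if (rec$status == "ok")
        panel <- panel_append(panel, target_date, hp_id, rec$absolute_error)
    }
  }
  forecast <- do.call(rbind, logs)
  class(forecast) <- c("forecast_log", "data.frame")
  list(forecast = forecast,
       selections = do.call(rbind, selections),
       panel = panel)
}
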