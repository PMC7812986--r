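#' Run the full forecasting pipeline
#'
#' Orchestrates the end-to-end workflow for one demand series: (optionally)
#' simulate or load the series and covariate calendar, build model
#' matrices, backtest every configured learner over the validation+test
#' blocks, apply the batch selection rules and/or online refit periods, fit
#' the convex stacker on validation-period predictions and score it on the
#' untouched test block, assemble the scoreboard, and (optionally) compute
#' permutation importance on the test rows. Deterministic given the config
#' seed; every output file name carries the config hash and seed, and a
#' metadata file records every defaulted convention (selection-rule `n` and
#' `alpha`, grids, clamping) so runs are auditable.
#'
#' @param config A [validate_run_config()]-validated `run_config` (or a
#'   bare list, validated here).
#' @param write Logical; write CSV/YAML artifacts to `config$output_dir`
#'   (default `TRUE`). The assembled objects are returned either way.
#' @return Invisibly, a list with elements `series`, `calendar`,
#'   `backtests` (per learner full-grid logs), `batch`, `online`,
#'   `stack` (weights + stacked test log), `scoreboard`, `importance`,
#'   `metadata`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_run_config(config)
  seed <- as.integer(cfg$seed)
  horizon <- cfg$horizons[1]

  if (!is.null(cfg$series_csv)) {
    series <- read_demand_series(cfg$series_csv)
    calendar <- read_covariate_calendar(cfg$calendar_csv)
  } else {
    syn <- do.call(synthetic_config,
                   modifyList(cfg$synthetic %||% list(), list(seed = seed)))
    gen <- generate_demand(syn)
    series <- gen$series; calendar <- gen$calendar
  }
  n <- nrow(series)
  need <- cfg$train_length + cfg$val_length + cfg$test_length + horizon - 1L
  if (need > n)
    stop_demandcast("pipeline: %d days needed but series has %d", need, n,
                    class = "demandcast_sizing_error")

  specs <- lapply(names(cfg$learners), function(nm) {
    grid <- cfg$learners[[nm]]
    if (is.null(grid)) learner_spec(nm) else learner_spec(nm, grid)
  })
  names(specs) <- names(cfg$learners)

  backtests <- list(); batch <- list(); online <- list()
  for (nm in names(specs)) {
    res <- tryCatch(
      run_batch_method(series, calendar, specs[[nm]],
                       rules = cfg$tuning$rules, horizon = horizon,
                       train_length = cfg$train_length,
                       val_length = cfg$val_length,
                       test_length = cfg$test_length,
                       seed = child_seed(seed, match(nm, names(specs)))),
      error = function(e) stop_demandcast(
        "pipeline stage 'batch' failed for learner %s: %s", nm,
        conditionMessage(e), class = "demandcast_stage_error"))
    backtests[[nm]] <- res$log
    batch[[nm]] <- res
    if (identical(cfg$tuning$method, "online") ||
        isTRUE(cfg$tuning$run_online)) {
      online[[nm]] <- lapply(cfg$tuning$periods, function(p)
        run_online_method(series, calendar, specs[[nm]], period = p,
                          horizon = horizon, val_log = res$log,
                          train_length = cfg$train_length,
                          val_length = cfg$val_length,
                          test_length = cfg$test_length,
                          seed = child_seed(seed, match(nm, names(specs)),
                                            p)))
      names(online[[nm]]) <- paste0("period", cfg$tuning$periods)
    }
  }

  # Stacker: per learner, the validation_average-selected setting's
  # daily-refit predictions; fitted on validation days, scored on test days.
  stack <- NULL
  if (isTRUE(cfg$stacking$enabled) && length(specs) >= 1L) {
    test_start <- series$date[n - cfg$test_length + 1L]
    per_learner <- lapply(names(specs), function(nm) {
      log <- backtests[[nm]]
      pan <- validation_panel(log[log$target_date < test_start, ,
                                  drop = FALSE])
      hp <- select_hyperparams(pan, "validation_average", test_start)
      log[log$hyperparam_id == hp, , drop = FALSE]
    })
    names(per_learner) <- names(specs)
    tab <- stacking_table(per_learner)
    fit_rows <- tab$dates < test_start
    ridge_opt <- cfg$stacking$ridge %||% "auto"
    weights <- if (identical(ridge_opt, "auto"))
      fit_stack_tuned(tab$predictions[fit_rows, , drop = FALSE],
                      tab$actuals[fit_rows])
    else
      fit_stack(tab$predictions[fit_rows, , drop = FALSE],
                tab$actuals[fit_rows], ridge = ridge_opt)
    test_rows <- which(!fit_rows & stats::complete.cases(tab$predictions))
    stacked_log <- forecast_log_row(
      tab$dates[test_rows], horizon, "stack", "stack",
      as.numeric(tab$predictions[test_rows, , drop = FALSE] %*%
                   as.numeric(weights)),
      tab$actuals[test_rows])
    class(stacked_log) <- c("forecast_log", "data.frame")
    stack <- list(weights = weights, forecast = stacked_log,
                  n_dropped = attr(weights, "n_dropped"))
  }

  test_logs <- lapply(batch, function(b) b$forecasts[[1]])
  names(test_logs) <- names(specs)
  if (!is.null(stack)) test_logs$stack <- stack$forecast
  board <- scoreboard(test_logs)

  importance <- NULL
  if (isTRUE(cfg$importance$enabled)) {
    inm <- cfg$importance$learner %||% "lm"
    if (inm %in% names(specs) && specs[[inm]]$family == "ml") {
      mm <- index_model_matrix(build_model_matrix(series, calendar, horizon),
                               series)
      fit_to <- n - cfg$test_length - horizon
      train_rows <- rows_in_targets(mm, fit_to - cfg$train_length -
                                      cfg$val_length + 1L, fit_to)
      hp <- select_hyperparams(
        validation_panel(backtests[[inm]][backtests[[inm]]$target_date <
          series$date[n - cfg$test_length + 1L], , drop = FALSE]),
        "validation_average", series$date[n - cfg$test_length + 1L])
      fitted <- fit_learner(specs[[inm]], hp,
                            list(rows = train_rows),
                            seed = child_seed(seed, 99L))
      test_rows <- rows_in_targets(mm, n - cfg$test_length + 1L, n)
      importance <- permutation_importance(
        fitted, test_rows, repeats = cfg$importance$repeats %||% 10L,
        seed = child_seed(seed, 98L))
    }
  }

  metadata <- list(
    config_hash = config_hash(cfg), seed = seed, horizon = horizon,
    n_days = n, train_length = cfg$train_length,
    val_length = cfg$val_length, test_length = cfg$test_length,
    rules = cfg$tuning$rules, rule_n = cfg$tuning$n,
    rule_alpha = cfg$tuning$alpha, periods = cfg$tuning$periods,
    stacking_ridge = if (!is.null(stack))
      attr(stack$weights, "ridge") %||% (cfg$stacking$ridge %||% 0)
    else cfg$stacking$ridge %||% "auto",
    importance_heldout = "test period",
    negative_forecast_clamp = 0,
    grids = lapply(specs, function(s) s$grid)
  )

  out <- list(series = series, calendar = calendar, backtests = backtests,
              batch = batch, online = online, stack = stack,
              scoreboard = board, importance = importance,
              metadata = metadata)
  if (write) write_pipeline_artifacts(out, cfg)
  invisible(out)
}

write_pipeline_artifacts <- function(out, cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste0(out$metadata$config_hash, "-seed", out$metadata$seed)
  fp <- function(stem) file.path(cfg$output_dir,
                                 paste0(stem, "-", tag, ".csv"))
  write_demand_series(out$series, fp("series"))
  write_covariate_calendar(out$calendar, fp("calendar"))
  for (nm in names(out$backtests))
    write_forecast_log(out$backtests[[nm]], fp(paste0("backtest-", nm)))
  for (nm in names(out$batch))
    write.csv(out$batch[[nm]]$selections,
              fp(paste0("selections-", nm)), row.names = FALSE)
  if (!is.null(out$stack)) {
    write.csv(data.frame(learner = names(out$stack$weights),
                         weight = as.numeric(out$stack$weights)),
              fp("stack-weights"), row.names = FALSE)
    write_forecast_log(out$stack$forecast, fp("stack-forecast"))
  }
  write.csv(as.data.frame(out$scoreboard), fp("scoreboard"),
            row.names = FALSE)
  if (!is.null(out$importance))
    write.csv(as.data.frame(out$importance), fp("importance"),
              row.names = FALSE)
  yaml::write_yaml(out$metadata,
                   file.path(cfg$output_dir,
                             paste0("metadata-", tag, ".yaml")))
  invisible(cfg$output_dir)
}
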