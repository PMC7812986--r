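#' Mean absolute error
#'
#' @param actuals,predictions Equal-length numeric vectors.
#' @return MAE in patients/day.
#' @export
mae <- function(actuals, predictions) {
  if (length(actuals) != length(predictions) || !length(actuals))
    stop_demandcast("mae: actuals and predictions must have equal nonzero length",
                    class = "demandcast_contract_error")
  mean(abs(actuals - predictions))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|actual - prediction| / actual)`; actuals must be strictly
#' positive (a zero count cannot be percentage-scored).
#'
#' @inheritParams mae
#' @return MAPE in percent.
#' @export
mape <- function(actuals, predictions) {
  if (length(actuals) != length(predictions) || !length(actuals))
    stop_demandcast("mape: actuals and predictions must have equal nonzero length",
                    class = "demandcast_contract_error")
  if (any(actuals <= 0))
    stop_demandcast("mape: all actuals must be > 0",
                    class = "demandcast_domain_error")
  100 * mean(abs(actuals - predictions) / actuals)
}

#' Score forecast logs into a comparison scoreboard
#'
#' Aggregates one or more `forecast_log`s into one row per configuration
#' with MAE (patients), MAPE (%), successful-record and skipped-record
#' counts, sorted ascending by MAE.
#'
#' @param logs A `forecast_log`, or a (possibly named) list of them; names
#'   become the `configuration` column (default: the learner name).
#' @param by Extra grouping columns present in the logs (default
#'   `c("learner", "horizon")`).
#' @return A `score_report` data frame.
#' @export
scoreboard <- function(logs, by = c("learner", "horizon")) {
  if (inherits(logs, "data.frame")) logs <- list(logs)
  if (is.null(names(logs)) || any(!nzchar(names(logs))))
    names(logs) <- vapply(logs, function(l)
      if (nrow(l)) l$learner[1] else "(empty)", "")
  rows <- lapply(names(logs), function(nm) {
    l <- logs[[nm]]
    if (!nrow(l)) {
      warning("empty forecast log: ", nm)
      return(NULL)
    }
    key <- interaction(l[by], drop = TRUE)
    do.call(rbind, lapply(levels(key), function(kv) {
      g <- l[key == kv, , drop = FALSE]
      ok <- g[g$status == "ok", , drop = FALSE]
      data.frame(configuration = nm,
                 learner = g$learner[1], horizon = g$horizon[1],
                 mae = if (nrow(ok)) mae(ok$actual, ok$prediction) else NA_real_,
                 mape = if (nrow(ok) && all(ok$actual > 0))
                   mape(ok$actual, ok$prediction) else NA_real_,
                 n_records = nrow(ok), n_skipped = sum(g$status != "ok"))
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(), class = c("score_report", "data.frame")))
  out <- out[order(out$mae), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("score_report", "data.frame"))
}

#' Permutation variable importance on held-out rows
#'
#' For a fitted ML learner and a held-out block of model-matrix rows:
#' permutes one raw feature column at a time (repeats times), measures the
#' mean increase in held-out MAE over the unpermuted baseline, floors
#' negative increases at zero and normalizes to percentages summing to 100.
#'
#' @param fitted A `fitted_learner` from the ML family.
#' @param rows Held-out `model_matrix` rows (not the fitting rows), with
#'   observed `demand`.
#' @param repeats Permutations per feature (default 10).
#' @param seed Integer seed (importances are seed-reproducible).
#' @param features Feature columns to score (default: all the matrix's
#'   feature columns).
#' @return An `importance_report` data frame (`feature`,
#'   `importance`, `raw_increase`), sorted by importance.
#' @export
permutation_importance <- function(fitted, rows, repeats = 10L, seed = 1L,
                                   features = attr(rows, "feature_cols")) {
  stopifnot(inherits(fitted, "fitted_learner"))
  if (fitted$spec$family != "ml")
    stop_demandcast(
      "permutation importance is defined for ML learners (got '%s')",
      fitted$spec$name, class = "demandcast_contract_error")
  if (repeats < 1L)
    stop_demandcast("repeats must be >= 1",
                    class = "demandcast_contract_error")
  missing_f <- setdiff(features, names(rows))
  if (length(missing_f))
    stop_demandcast("feature '%s' absent from the model matrix",
                    missing_f[1], class = "demandcast_contract_error")
  rows <- rows[!is.na(rows$demand), , drop = FALSE]
  baseline <- mae(rows$demand, predict_learner(fitted, rows))
  n <- nrow(rows)
  inc <- with_seed(seed, vapply(features, function(f) {
    errs <- vapply(seq_len(repeats), function(r) {
      perm <- rows
      perm[[f]] <- perm[[f]][sample.int(n)]
      mae(perm$demand, predict_learner(fitted, perm))
    }, 0)
    mean(errs) - baseline
  }, 0))
  inc <- pmax(inc, 0)
  pct <- if (sum(inc) > 0) 100 * inc / sum(inc) else rep(0, length(inc))
  out <- data.frame(feature = features, importance = unname(pct),
                    raw_increase = unname(inc))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, baseline_mae = baseline,
            class = c("importance_report", "data.frame"))
}

#' Exploratory diagnostics of a demand series
#'
#' Computes (i) an additive loess-based seasonal-trend decomposition at
#' weekly period 7 (`data = trend + seasonal + remainder` exactly), (ii)
#' day-of-week and monthly mean attendance profiles, and (iii) the
#' autocorrelation sequence of the counts.
#'
#' @param series A `demand_series` of at least 2 full years (730 days).
#' @param lag_max Largest autocorrelation lag (default 28).
#' @return A `demand_diagnostics` list: `decomposition` (data frame with
#'   `date`, `data`, `trend`, `seasonal`, `remainder`), `weekday_profile`,
#'   `monthly_profile`, `acf` (data frame `lag`, `acf` with `acf[lag 0] = 1`).
#' @export
demand_diagnostics <- function(series, lag_max = 28L) {
  validate_demand_series(series)
  n <- nrow(series)
  if (n < 730L)
    stop_demandcast(
      "diagnostics need at least 2 full years (730 days); got %d", n,
      class = "demandcast_sizing_error")
  y <- ts(as.numeric(series$count), frequency = 7)
  dec <- stl(y, s.window = "periodic")
  seasonal <- as.numeric(dec$time.series[, "seasonal"])
  trend <- as.numeric(dec$time.series[, "trend"])
  remainder <- as.numeric(series$count) - trend - seasonal
  wd <- factor(weekday_names()[as.integer(format(series$date, "%u"))],
               levels = weekday_names())
  mo <- factor(months_abbr()[as.integer(format(series$date, "%m"))],
               levels = months_abbr())
  a <- acf(series$count, lag.max = lag_max, plot = FALSE)
  structure(list(
    decomposition = data.frame(date = series$date,
                               data = as.numeric(series$count),
                               trend = trend, seasonal = seasonal,
                               remainder = remainder),
    weekday_profile = tapply(series$count, wd, mean),
    monthly_profile = tapply(series$count, mo, mean),
    acf = data.frame(lag = as.numeric(a$lag), acf = as.numeric(a$acf))
  ), class = "demand_diagnostics")
}
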