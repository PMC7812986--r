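#' Scaled linear time index
#'
#' Maps day positions within a training window onto a dimensionless linear
#' index centred on the window: position `(L + 1) / 2` maps to 0, the first
#' and last training positions map to -0.5 and +0.5 up to a half-step of
#' `1 / (2L)`, and consecutive positions differ by exactly `1 / L`.
#' Positions beyond the window extrapolate linearly (used for target dates
#' past the origin).
#'
#' @param train_window_length Number of days in the training window (> 0).
#' @param position 1-based day offset(s).
#' @return Numeric index value(s).
#' @export
scaled_time_index <- function(train_window_length, position) {
  if (!is.numeric(train_window_length) || train_window_length <= 0)
    stop_demandcast("train_window_length must be positive",
                    class = "demandcast_config_error")
  (position - (train_window_length + 1) / 2) / train_window_length
}

#' Build the lagged-covariate model matrix
#'
#' One row per eligible target date, for a fixed forecast horizon. Each
#' row's lagged-demand features depend only on counts dated at or before
#' its origin (`target - horizon`):
#' \describe{
#'   \item{yesterday}{count at the origin — the most recent observed day.
#'     At horizons 3 and 7 the literal previous day is unobserved at
#'     prediction time, so the origin value stands in for it.}
#'   \item{same_day_last_week}{count at exactly `target - 7` days (observed
#'     because horizon <= 7).}
#'   \item{average_of_previous_week}{mean of the 7 most recent observed
#'     counts, i.e. days `origin - 6 .. origin`.}
#' }
#' Calendar covariates (`bank_holiday`, `school_holiday`, event flags,
#' `month`, `day_of_week`) are taken at the target date. Weather and
#' flu-search covariates are taken at `target - 1` even for multi-day
#' horizons, modelling the operational assumption that short-range weather
#' forecasts and search trends are available at prediction time. `time` is
#' the [scaled_time_index()] over the full series. Target dates whose lags
#' precede the series start are excluded; targets up to `horizon` days past
#' the series end are included with `demand = NA` (prediction rows).
#'
#' @param series A `demand_series` (columns `date`, `count`).
#' @param calendar A `covariate_calendar` covering the series dates through
#'   `horizon` days past its end.
#' @param horizon Forecast horizon in days: 1, 3 or 7.
#' @return A `model_matrix` data frame with attributes `horizon` and
#'   `feature_cols` (the predictor columns, in their fixed order).
#' @export
build_model_matrix <- function(series, calendar, horizon) {
  horizon <- as.integer(horizon)
  if (!horizon %in% c(1L, 3L, 7L))
    stop_demandcast("unsupported horizon %d: must be one of 1, 3, 7",
                    horizon, class = "demandcast_horizon_error")
  validate_demand_series(series)
  n <- nrow(series)
  if (n < 7L + horizon)
    stop_demandcast("series length %d too short for horizon %d (need >= %d)",
                    n, horizon, 7L + horizon,
                    class = "demandcast_sizing_error")
  dates <- series$date
  all_targets <- seq.int(max(horizon + 7L, 8L), n + horizon)
  target_dates <- dates[1] + (all_targets - 1L)
  ci <- match(target_dates, calendar$date)
  cprev <- match(target_dates - 1L, calendar$date)
  if (anyNA(ci) || anyNA(cprev))
    stop_demandcast(
      "calendar does not cover the series dates (missing %s)",
      format((target_dates[which(is.na(ci) | is.na(cprev))])[1]),
      class = "demandcast_alignment_error")

  counts <- series$count
  origin <- all_targets - horizon
  prev_week <- vapply(origin, function(o) mean(counts[(o - 6L):o]), 0)
  mm <- data.frame(
    target_date = target_dates,
    origin_date = dates[1] + (origin - 1L),
    horizon = horizon,
    demand = ifelse(all_targets <= n, counts[pmin(all_targets, n)], NA_real_),
    month = factor(months_abbr()[as.integer(format(target_dates, "%m"))],
                   levels = months_abbr()),
    yesterday = counts[origin],
    same_day_last_week = counts[all_targets - 7L],
    average_of_previous_week = prev_week,
    time = scaled_time_index(n, all_targets),
    bank_holiday = calendar$bank_holiday[ci],
    school_holiday = calendar$school_holiday[ci],
    day_of_week = factor(weekday_names()[as.integer(format(target_dates, "%u"))],
                         levels = weekday_names()),
    precipitation_prev = calendar$precipitation[cprev],
    tmax_prev = calendar$tmax[cprev],
    tmin_prev = calendar$tmin[cprev],
    flu_prev = calendar$flu_hits[cprev]
  )
  event_cols <- setdiff(names(calendar),
                        c("date", "bank_holiday", "school_holiday",
                          "precipitation", "tmax", "tmin", "flu_hits"))
  for (ev in event_cols) mm[[ev]] <- calendar[[ev]][ci]
  feature_cols <- c("yesterday", "same_day_last_week",
                    "average_of_previous_week", "time", "month",
                    "day_of_week", "bank_holiday", "school_holiday",
                    "precipitation_prev", "tmax_prev", "tmin_prev",
                    "flu_prev", event_cols)
  structure(mm,
            horizon = horizon,
            feature_cols = feature_cols,
            class = c("model_matrix", "data.frame"))
}

months_abbr <- function() {
  c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
    "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
}

validate_demand_series <- function(series) {
  if (!all(c("date", "count") %in% names(series)))
    stop_demandcast("demand series needs 'date' and 'count' columns",
                    class = "demandcast_alignment_error")
  d <- as.integer(diff(series$date))
  if (length(d) && any(d != 1L)) {
    gap <- series$date[which(d != 1L)[1]] + 1L
    stop_demandcast("demand series has a date gap: missing %s", format(gap),
                    class = "demandcast_gap_error")
  }
  if (any(series$count < 0, na.rm = TRUE))
    stop_demandcast("demand series has negative counts",
                    class = "demandcast_alignment_error")
  invisible(series)
}

# Numeric one-hot design used by every ML learner: month and day_of_week
# expand to indicators with January / Monday as reference levels; logical
# flags become 0/1. Column set is fixed regardless of which levels appear.
ml_design <- function(rows, feature_cols = attr(rows, "feature_cols")) {
  out <- list()
  for (col in feature_cols) {
    v <- rows[[col]]
    if (is.factor(v)) {
      lev <- levels(v)
      for (l in lev[-1]) out[[paste0(col, "_", l)]] <- as.numeric(v == l)
    } else if (is.logical(v)) {
      out[[col]] <- as.numeric(v)
    } else {
      out[[col]] <- as.numeric(v)
    }
  }
  do.call(cbind, out)
}
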