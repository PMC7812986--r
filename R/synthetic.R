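#' Configuration for the synthetic ED-attendance generator
#'
#' Describes a synthetic daily emergency-department attendance process with
#' the structure typical of real ED series: a slowly varying trend, strong
#' day-of-week effects (Monday peak, weekend trough), winter-peaked annual
#' seasonality, holiday and one-off event effects, coupling to weather and
#' flu-related search volume, and overdispersed count noise.
#'
#' Effects combine additively on the mean (patients/day) scale; the
#' structural mean is clamped at a small positive floor before sampling.
#' Counts are drawn from a negative binomial distribution with mean equal to
#' the structural mean and variance `mu * (1 + dispersion * mu)`.
#' `dispersion = 0` is the degenerate noise-free case: counts are
#' `round(mu)` exactly.
#'
#' @param n_days Number of consecutive days to simulate (>= 1).
#' @param start_date First date of the series (a `Date` or ISO-8601 string).
#' @param base_level Mean patients/day when all effects are zero (> 0).
#' @param trend Piecewise-linear trend: a list with `slopes` (one or two
#'   slopes, patients/day/year) and optional `breakpoint` (fraction of the
#'   span in `(0, 1)`, used when two slopes are given). The trend term is
#'   centred to mean zero over the span so `base_level` remains the average
#'   level.
#' @param weekday_effects Named numeric vector of 7 additive offsets
#'   (patients), names Monday..Sunday. Defaults peak on Monday and trough at
#'   the weekend.
#' @param annual_amplitude Amplitude (patients) of the annual cosine,
#'   peaking in winter (`annual_peak_yday`).
#' @param annual_peak_yday Day-of-year of the annual peak (default 1,
#'   i.e. early January).
#' @param holiday_effect Additive offset (patients) applied on any day
#'   flagged as a bank or school holiday.
#' @param events Named list of one-off surge events; each element is a list
#'   with `dates` (Date vector) and `effect` (patients). Defaults define a
#'   late-August carnival surge and a Christmas-day drop.
#' @param weather_coupling Named numeric coefficients `precipitation`
#'   (patients/mm), `tmax`, `tmin` (patients/degree C); applied to the
#'   previous day's covariate values centred at their seasonal expectation,
#'   so they perturb rather than shift the mean level, and act as leading
#'   indicators exactly as the model matrix's previous-day covariates do.
#' @param flu_coupling Patients per unit of the previous day's (centred)
#'   relative flu search volume.
#' @param dispersion Negative-binomial dispersion (>= 0); see Details.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config (the seed is part of the config).
#' @return An object of class `synthetic_config`.
#' @seealso [generate_demand()], [structural_mean()], [st_marys_config()]
#' @export
synthetic_config <- function(n_days = 2920L,
                             start_date = "2011-01-03",
                             base_level = 208,
                             trend = list(slopes = c(-3, 3), breakpoint = 0.5),
                             weekday_effects = c(Monday = 18, Tuesday = 6,
                                                 Wednesday = 2, Thursday = 2,
                                                 Friday = 0, Saturday = -12,
                                                 Sunday = -16),
                             annual_amplitude = 8,
                             annual_peak_yday = 1L,
                             holiday_effect = -10,
                             events = default_events(start_date, n_days),
                             weather_coupling = c(precipitation = 0.3,
                                                  tmax = -0.2, tmin = 0),
                             flu_coupling = 0.15,
                             dispersion = 0.004,
                             seed = 20110103L) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L)
    stop_demandcast("invalid config field 'n_days': must be >= 1",
                    class = "demandcast_config_error")
  if (!is.numeric(base_level) || base_level <= 0)
    stop_demandcast("invalid config field 'base_level': must be > 0",
                    class = "demandcast_config_error")
  if (length(weekday_effects) != 7L)
    stop_demandcast(
      "invalid config field 'weekday_effects': exactly 7 entries required",
      class = "demandcast_config_error")
  if (is.null(names(weekday_effects)))
    names(weekday_effects) <- weekday_names()
  if (!setequal(names(weekday_effects), weekday_names()))
    stop_demandcast(
      "invalid config field 'weekday_effects': names must be Monday..Sunday",
      class = "demandcast_config_error")
  if (!is.numeric(dispersion) || dispersion < 0)
    stop_demandcast("invalid config field 'dispersion': must be >= 0",
                    class = "demandcast_config_error")
  if (!is.list(trend) || is.null(trend$slopes) || !length(trend$slopes))
    stop_demandcast("invalid config field 'trend': needs numeric 'slopes'",
                    class = "demandcast_config_error")
  structure(list(
    n_days = n_days,
    start_date = as.Date(start_date),
    base_level = base_level,
    trend = trend,
    weekday_effects = weekday_effects[weekday_names()],
    annual_amplitude = annual_amplitude,
    annual_peak_yday = as.integer(annual_peak_yday),
    holiday_effect = holiday_effect,
    events = events,
    weather_coupling = weather_coupling,
    flu_coupling = flu_coupling,
    dispersion = dispersion,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

weekday_names <- function() {
  c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
    "Saturday", "Sunday")
}

#' Ready-made configs calibrated to the two London EDs' published summaries
#'
#' `st_marys_config()` targets an average demand near 208 patients/day with a
#' down-then-up trend; `charing_cross_config()` targets an average near 106
#' with an upward trend. Only the published mean levels and qualitative
#' shapes are emulated; variances and couplings are calibration choices.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
st_marys_config <- function(...) {
  synthetic_config(...)
}

#' @rdname st_marys_config
#' @export
charing_cross_config <- function(...) {
  args <- modifyList(list(
    base_level = 106,
    trend = list(slopes = c(2.5)),
    weekday_effects = c(Monday = 10, Tuesday = 4, Wednesday = 1, Thursday = 1,
                        Friday = 0, Saturday = -7, Sunday = -9),
    annual_amplitude = 4,
    holiday_effect = -6,
    flu_coupling = 0.08,
    seed = 20110104L
  ), list(...))
  do.call(synthetic_config, args)
}

#' Default one-off surge events (carnival and Christmas)
#'
#' Carnival: the last Monday of August each year, +40 patients. Christmas:
#' 25 December each year, -25 patients (EDs typically see a Christmas-day
#' dip followed by a winter surge captured by the annual term).
#'
#' @param start_date,n_days Span the events should cover.
#' @return Named list of events, each `list(dates, effect)`.
#' @export
default_events <- function(start_date, n_days) {
  start_date <- as.Date(start_date)
  dates <- seq(start_date, by = "day", length.out = n_days + 7L)
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  carnival <- as.Date(vapply(years, function(y) {
    aug <- seq(as.Date(sprintf("%d-08-25", y)), as.Date(sprintf("%d-08-31", y)),
               by = "day")
    as.character(aug[format(aug, "%u") == "1"])
  }, character(1)))
  christmas <- as.Date(sprintf("%d-12-25", years))
  list(
    carnival = list(dates = carnival[carnival %in% dates], effect = 40),
    christmas = list(dates = christmas[christmas %in% dates], effect = -25)
  )
}

# ---- calendars -------------------------------------------------------------

# UK-style bank holiday rules: New Year's Day, first and last Monday of May,
# last Monday of August, Christmas Day, Boxing Day.
bank_holiday_dates <- function(dates) {
  yday <- format(dates, "%m-%d")
  u <- as.integer(format(dates, "%u"))
  fixed <- yday %in% c("01-01", "12-25", "12-26")
  month <- as.integer(format(dates, "%m"))
  dom <- as.integer(format(dates, "%d"))
  may_first_mon <- month == 5L & u == 1L & dom <= 7L
  may_last_mon <- month == 5L & u == 1L & dom >= 25L
  aug_last_mon <- month == 8L & u == 1L & dom >= 25L
  fixed | may_first_mon | may_last_mon | aug_last_mon
}

# English-style school holiday rules: summer, Christmas, Easter-time and
# three half-term weeks.
school_holiday_dates <- function(dates) {
  md <- format(dates, "%m-%d")
  in_range <- function(a, b) md >= a & md <= b
  in_range("07-20", "08-31") | md >= "12-20" | md <= "01-03" |
    in_range("04-01", "04-14") | in_range("02-14", "02-21") |
    in_range("05-28", "06-04") | in_range("10-25", "11-01")
}

# Seasonal expectations of the weather/flu processes; couplings are applied
# to covariates centred at these so they add variability, not level shift.
weather_seasonal_mean <- function(yday) {
  phase <- 2 * pi * (yday - 196) / 365.25  # warmest mid-July
  list(tmax = 14 + 8 * cos(phase), gap = 6.5, precip = 1.8)
}

flu_seasonal_shape <- function(yday) {
  # winter-peaked, strictly positive
  pmax(0, cos(2 * pi * (yday - 15) / 365.25))^3
}

#' Generate the synthetic covariate calendar
#'
#' Deterministic given the config seed. Weather covariates are seasonal
#' sinusoids plus noise (with `tmin <= tmax` by construction); `flu_hits` is
#' a winter-peaked positive autocorrelated process rescaled to `[0, 100]`;
#' bank and school holidays come from fixed date rules; event flags are one
#' logical column per configured event. The calendar extends 7 days past the
#' demand series so feature rows for true future targets can be built.
#'
#' @param config A [synthetic_config()].
#' @return A `covariate_calendar` data frame.
#' @export
generate_calendar <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_days + 7L
  dates <- seq(config$start_date, by = "day", length.out = n)
  yday <- as.integer(format(dates, "%j"))
  sm <- weather_seasonal_mean(yday)
  with_seed(child_seed(config$seed, 1L), {
    tmax <- sm$tmax + rnorm(n, 0, 2.5)
    tmin <- tmax - pmax(0.5, sm$gap + rnorm(n, 0, 1.5))
    wet <- runif(n) < 0.45
    precipitation <- ifelse(wet, rgamma(n, shape = 1.1, scale = sm$precip / 0.5), 0)
    flu_raw <- flu_seasonal_shape(yday) * 60 +
      as.numeric(stats::filter(rnorm(n, 0, 6), 0.8, method = "recursive"))
    flu_hits <- pmin(100, pmax(0, flu_raw))
  })
  cal <- data.frame(
    date = dates,
    bank_holiday = bank_holiday_dates(dates),
    school_holiday = school_holiday_dates(dates),
    precipitation = round(precipitation, 2),
    tmax = round(tmax, 1),
    tmin = round(tmin, 1),
    flu_hits = round(flu_hits, 2)
  )
  for (ev in names(config$events)) {
    cal[[ev]] <- dates %in% as.Date(config$events[[ev]]$dates)
  }
  class(cal) <- c("covariate_calendar", "data.frame")
  cal
}

# Centred covariate anomalies used by the coupling terms.
covariate_anomalies <- function(cal) {
  yday <- as.integer(format(cal$date, "%j"))
  sm <- weather_seasonal_mean(yday)
  list(
    precipitation = cal$precipitation - sm$precip * 0.45 * 2.2,
    tmax = cal$tmax - sm$tmax,
    tmin = cal$tmin - (sm$tmax - sm$gap),
    flu = cal$flu_hits - mean(cal$flu_hits)
  )
}

trend_term <- function(config, t_index) {
  n <- config$n_days
  slopes <- config$trend$slopes / 365.25  # patients/day
  tt <- as.double(t_index)
  full <- seq_len(n)
  raw_at <- function(x) {
    if (length(slopes) == 1L) return(slopes[1] * x)
    bp <- round((config$trend$breakpoint %||% 0.5) * n)
    ifelse(x <= bp, slopes[1] * x, slopes[1] * bp + slopes[2] * (x - bp))
  }
  raw_at(tt) - mean(raw_at(full))
}

#' Structural (noise-free) mean attendance for given dates
#'
#' The expected patients/day implied by a config: base level plus centred
#' trend, weekday, annual, holiday, event, weather-coupling and
#' flu-coupling terms, floored at 1 patient/day. A pure function of the
#' config and the date (the covariates are themselves deterministic given
#' the config seed).
#'
#' @param config A [synthetic_config()].
#' @param dates Dates within the configured span.
#' @param calendar Optionally, a pre-generated [generate_calendar()] output
#'   (avoids regenerating it in tight loops).
#' @return Numeric vector of expected patients/day.
#' @export
structural_mean <- function(config, dates, calendar = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  dates <- as.Date(dates)
  span <- seq(config$start_date, by = "day", length.out = config$n_days)
  t_index <- as.integer(dates - config$start_date) + 1L
  if (any(t_index < 1L | t_index > config$n_days))
    stop_demandcast("date outside the configured span [%s, %s]",
                    format(min(span)), format(max(span)),
                    class = "demandcast_range_error")
  cal <- calendar %||% generate_calendar(config)
  i <- match(dates, cal$date)
  # weather/flu couple with a one-day lag (leading-indicator semantics,
  # matching the previous-day covariates of the model matrix); the first
  # calendar day, which has no predecessor, falls back to its own value
  ip <- match(dates - 1L, cal$date)
  ip[is.na(ip)] <- i[is.na(ip)]
  an <- covariate_anomalies(cal)
  wd <- config$weekday_effects[as.integer(format(dates, "%u"))]
  yday <- as.integer(format(dates, "%j"))
  annual <- config$annual_amplitude *
    cos(2 * pi * (yday - config$annual_peak_yday) / 365.25)
  holiday <- ifelse(cal$bank_holiday[i] | cal$school_holiday[i],
                    config$holiday_effect, 0)
  event <- numeric(length(dates))
  for (ev in names(config$events)) {
    event <- event + config$events[[ev]]$effect *
      (dates %in% as.Date(config$events[[ev]]$dates))
  }
  wc <- config$weather_coupling
  weather <- (wc["precipitation"] %||% 0) * an$precipitation[ip] +
    (wc["tmax"] %||% 0) * an$tmax[ip] + (wc["tmin"] %||% 0) * an$tmin[ip]
  flu <- config$flu_coupling * an$flu[ip]
  mu <- config$base_level + trend_term(config, t_index) + unname(wd) +
    annual + holiday + event + as.numeric(weather) + flu
  pmax(mu, 1)
}

#' Generate a synthetic demand series and covariate calendar
#'
#' Draws daily attendance counts from a negative binomial distribution
#' around the structural mean (see [synthetic_config()] for the noise
#' model). Deterministic given the config (seed included).
#'
#' @param config A [synthetic_config()].
#' @return A list with `series` (a `demand_series` data frame: `date`,
#'   `count`) and `calendar` (a `covariate_calendar`).
#' @export
generate_demand <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cal <- generate_calendar(config)
  dates <- seq(config$start_date, by = "day", length.out = config$n_days)
  mu <- structural_mean(config, dates, calendar = cal)
  counts <- if (config$dispersion == 0) {
    round(mu)
  } else {
    with_seed(child_seed(config$seed, 2L),
              rnbinom(config$n_days, mu = mu, size = 1 / config$dispersion))
  }
  series <- data.frame(date = dates, count = as.integer(counts))
  class(series) <- c("demand_series", "data.frame")
  list(series = series, calendar = cal)
}
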