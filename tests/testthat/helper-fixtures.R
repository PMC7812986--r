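# Shared fixtures: everything is generated in code at test time.

# Small synthetic world with default St Mary's-like structure.
quick_world <- function(n_days = 260L, seed = 101L, ...) {
  cfg <- st_marys_config(n_days = n_days, seed = seed, ...)
  c(generate_demand(cfg), list(config = cfg))
}

# A config whose only structure is chosen by the caller: all effects off
# unless overridden.
bare_config <- function(n_days = 120L, seed = 7L, ...) {
  synthetic_config(
    n_days = n_days, base_level = 150,
    trend = list(slopes = 0),
    weekday_effects = stats::setNames(rep(0, 7),
      c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
        "Saturday", "Sunday")),
    annual_amplitude = 0, holiday_effect = 0,
    events = list(),
    weather_coupling = c(precipitation = 0, tmax = 0, tmin = 0),
    flu_coupling = 0, dispersion = 0, seed = seed, ...)
}

# Deterministic toy series: counts 1..n on consecutive days.
toy_series <- function(n = 14L, start = as.Date("2015-06-01"),
                       counts = seq_len(n)) {
  s <- data.frame(date = start + seq_len(n) - 1L,
                  count = as.integer(counts))
  class(s) <- c("demand_series", "data.frame")
  s
}

# Flat covariate calendar covering a series plus padding.
flat_calendar <- function(series, pad = 7L) {
  dates <- seq(series$date[1], by = "day",
               length.out = nrow(series) + pad)
  cal <- data.frame(date = dates, bank_holiday = FALSE,
                    school_holiday = FALSE, precipitation = 0,
                    tmax = 15, tmin = 8, flu_hits = 10,
                    carnival = FALSE, christmas = FALSE)
  class(cal) <- c("covariate_calendar", "data.frame")
  cal
}

# Small grids so contract tests over all nine learners stay fast.
small_grid <- function(name) {
  switch(name,
    arima = default_grid("arima")[1:2],
    glmnet = list(list(mixture = 0, lambda = 0.1),
                  list(mixture = 1, lambda = 1)),
    rf = list(list(mtry = "sqrt", num_trees = 100L)),
    gbm = list(list(trees = 50L, depth = 2L, learning_rate = 0.1)),
    knn = list(list(k = 3L), list(k = 7L)),
    default_grid(name))
}

small_spec <- function(name) learner_spec(name, grid = small_grid(name))

# Replace all counts after day `origin_idx` with a shuffled decoy — the
# corruption used by the blindness property tests.
corrupt_after <- function(series, origin_idx, seed = 999L) {
  n <- nrow(series)
  if (origin_idx >= n) return(series)
  idx <- (origin_idx + 1L):n
  set.seed(seed)
  series$count[idx] <- series$count[idx] +
    sample(c(-50L, 37L, 81L, -23L), length(idx), replace = TRUE)
  series$count <- pmax(series$count, 0L)
  series
}

# Hand-built validation panel from an error matrix (rows = dates).
panel_from_matrix <- function(err, start = as.Date("2018-01-01"),
                              ids = sprintf("hp%02d", seq_len(ncol(err)))) {
  long <- data.frame(
    date = rep(start + seq_len(nrow(err)) - 1L, times = ncol(err)),
    hyperparam_id = rep(ids, each = nrow(err)),
    absolute_error = as.numeric(err))
  log <- data.frame(target_date = long$date, horizon = 1L,
                    learner = "stub", hyperparam_id = long$hyperparam_id,
                    prediction = 0, actual = long$absolute_error,
                    absolute_error = long$absolute_error,
                    status = "ok", reason = NA_character_)
  validation_panel(log)
}

# Brute-force simplex grid search used as the stacking oracle.
stack_grid_oracle <- function(P, y, step = 0.01) {
  K <- ncol(P)
  stopifnot(K <= 3)
  grid <- seq(0, 1, by = step)
  best <- Inf
  if (K == 1) return(sum((y - P[, 1])^2))
  for (w1 in grid) {
    if (K == 2) {
      w <- c(w1, 1 - w1)
      best <- min(best, sum((y - P %*% w)^2))
    } else {
      for (w2 in seq(0, 1 - w1, by = step)) {
        w <- c(w1, w2, 1 - w1 - w2)
        best <- min(best, sum((y - P %*% w)^2))
      }
    }
  }
  best
}
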