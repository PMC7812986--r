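# World with one deliberately dominant engineered covariate: demand is
# driven overwhelmingly by previous-day precipitation (5 patients/mm), a
# covariate with year-round variance and no autocorrelation, so it cannot
# be proxied by the demand lags; other structure off, light noise.
rain_world <- function(n_days = 220L, seed = 41L) {
  cfg <- bare_config(n_days, seed = seed)
  cfg$weather_coupling <- c(precipitation = 5, tmax = 0, tmin = 0)
  cfg$dispersion <- 0.0005
  c(generate_demand(cfg), list(config = cfg))
}

test_that("mae matches hand arithmetic and is permutation-invariant", {
  expect_equal(mae(c(100, 200), c(100, 200)), 0)
  expect_equal(mae(c(100, 200), c(110, 180)), 15)
  set.seed(1)
  a <- rnorm(30, 100); p <- rnorm(30, 100)
  o <- sample(30)
  expect_equal(mae(a, p), mae(a[o], p[o]))
  expect_error(mae(1:3, 1:2), class = "demandcast_contract_error")
})

test_that("mape matches hand arithmetic and is scale-invariant", {
  expect_equal(mape(c(100, 200), c(100, 200)), 0)
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  set.seed(2)
  a <- runif(20, 50, 250); p <- runif(20, 50, 250)
  expect_equal(mape(3 * a, 3 * p), mape(a, p))
  expect_error(mape(c(100, 0), c(90, 10)),
               class = "demandcast_domain_error")
})

test_that("scoreboard ranks configurations by MAE and conserves counts", {
  d <- as.Date("2019-01-01") + 0:9
  mk <- function(nm, err, skip = 0L) {
    status <- c(rep("ok", 10 - skip), rep("skipped", skip))
    out <- data.frame(target_date = d, horizon = 1L, learner = nm,
                      hyperparam_id = "hp01",
                      prediction = ifelse(status == "ok", 100 + err, NA),
                      actual = 100,
                      absolute_error = ifelse(status == "ok", abs(err), NA),
                      status = status, reason = NA_character_)
    class(out) <- c("forecast_log", "data.frame")
    out
  }
  board <- scoreboard(list(worse = mk("a", rep(8, 10)),
                           better = mk("b", rep(3, 10), skip = 2L)))
  expect_identical(board$configuration, c("better", "worse"))
  expect_equal(board$mae, c(3, 8))
  expect_equal(board$mape, c(3, 8))
  expect_equal(board$n_records, c(8L, 10L))
  expect_equal(board$n_skipped, c(2L, 0L))
  # merging two disjoint logs concatenates their report rows
  both <- scoreboard(list(a = mk("a", rep(8, 10)), b = mk("b", rep(3, 10))))
  expect_equal(sum(both$n_records), 20L)
  expect_warning(scoreboard(list(empty = mk("a", 1)[0, ])), "empty")
})

test_that("single-record scoreboard echoes that error", {
  log <- data.frame(target_date = as.Date("2019-01-01"), horizon = 1L,
                    learner = "lm", hyperparam_id = "hp01",
                    prediction = 195, actual = 200, absolute_error = 5,
                    status = "ok", reason = NA_character_)
  class(log) <- c("forecast_log", "data.frame")
  board <- scoreboard(log)
  expect_equal(board$mae, 5)
  expect_equal(board$mape, 2.5)
})

test_that("importance percentages are normalized, floored and reproducible", {
  w <- rain_world()
  mm <- build_model_matrix(w$series, w$calendar, 1L)
  train <- mm[20:150, ]; attr(train, "feature_cols") <- attr(mm, "feature_cols")
  heldout <- mm[151:200, ]; attr(heldout, "feature_cols") <- attr(mm, "feature_cols")
  fitted <- fit_learner(learner_spec("lm"), list(), list(rows = train))
  imp1 <- permutation_importance(fitted, heldout, repeats = 5L, seed = 9L)
  imp2 <- permutation_importance(fitted, heldout, repeats = 5L, seed = 9L)
  expect_identical(imp1, imp2)
  expect_true(all(imp1$importance >= 0))
  expect_equal(sum(imp1$importance), 100, tolerance = 1e-6)
})

test_that("the dominant engineered covariate ranks first for lm", {
  w <- rain_world()
  mm <- build_model_matrix(w$series, w$calendar, 1L)
  train <- mm[20:150, ]; attr(train, "feature_cols") <- attr(mm, "feature_cols")
  heldout <- mm[151:200, ]; attr(heldout, "feature_cols") <- attr(mm, "feature_cols")
  fitted <- fit_learner(learner_spec("lm"), list(), list(rows = train))
  imp <- permutation_importance(fitted, heldout, repeats = 10L, seed = 3L)
  expect_identical(imp$feature[1], "precipitation_prev")
  expect_gt(imp$importance[1], 30)
})

test_that("a feature the model ignores has near-zero importance", {
  w <- rain_world()
  mm <- build_model_matrix(w$series, w$calendar, 1L)
  # restrict lm to two features; an untouched third must score ~0
  fc <- c("precipitation_prev", "yesterday")
  train <- mm[20:150, ]; attr(train, "feature_cols") <- fc
  heldout <- mm[151:200, ]; attr(heldout, "feature_cols") <- fc
  fitted <- fit_learner(learner_spec("lm"), list(), list(rows = train))
  imp <- permutation_importance(fitted, heldout, seed = 5L,
                                features = c(fc, "tmax_prev"))
  expect_equal(imp$raw_increase[imp$feature == "tmax_prev"], 0)
  # single-feature model: that feature carries 100%
  fc1 <- "precipitation_prev"
  train1 <- mm[20:150, ]; attr(train1, "feature_cols") <- fc1
  fitted1 <- fit_learner(learner_spec("lm"), list(), list(rows = train1))
  held1 <- heldout; attr(held1, "feature_cols") <- fc1
  imp1 <- permutation_importance(fitted1, held1, seed = 5L)
  expect_equal(imp1$importance, 100)
})

test_that("importance rejects ts learners, bad repeats and absent features", {
  w <- rain_world()
  mm <- build_model_matrix(w$series, w$calendar, 1L)
  train <- mm[20:150, ]; attr(train, "feature_cols") <- attr(mm, "feature_cols")
  ts_fit <- fit_learner(learner_spec("ets"), list(),
                        list(counts = w$series$count[1:100]))
  expect_error(permutation_importance(ts_fit, mm),
               class = "demandcast_contract_error")
  lm_fit <- fit_learner(learner_spec("lm"), list(), list(rows = train))
  expect_error(permutation_importance(lm_fit, train, repeats = 0L),
               class = "demandcast_contract_error")
  expect_error(permutation_importance(lm_fit, train,
                                      features = "not_a_feature"),
               class = "demandcast_contract_error")
})

test_that("diagnostics decompose additively and expose weekly structure", {
  gen <- quick_world(800L, seed = 43L)
  d <- demand_diagnostics(gen$series)
  rec <- with(d$decomposition, data - trend - seasonal - remainder)
  expect_lt(max(abs(rec)), 1e-8)
  expect_equal(d$acf$acf[d$acf$lag == 0], 1)
  expect_gt(d$acf$acf[d$acf$lag == 7], d$acf$acf[d$acf$lag == 3])
  expect_equal(which.max(d$weekday_profile), c(Monday = 1L))
  expect_length(d$monthly_profile, 12L)
  expect_error(demand_diagnostics(gen$series[1:100, ]),
               class = "demandcast_sizing_error")
})

test_that("a pure weekly cycle leaves a negligible remainder", {
  cycle <- rep(c(130, 150, 140, 120, 110, 90, 80), 110)
  s <- toy_series(length(cycle), counts = cycle)
  d <- demand_diagnostics(s)
  expect_lt(max(abs(d$decomposition$remainder)), 1e-6)
  prof <- as.numeric(d$weekday_profile)
  expect_equal(diff(range(prof)), 70)  # cycle span reproduced
})
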