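# Shared world for learner tests: moderate noise, full structure.
world <- quick_world(160L, seed = 23L)
mm1 <- build_model_matrix(world$series, world$calendar, 1L)

train_data_for <- function(spec, n_train = 120L, horizon = 1L) {
  counts <- world$series$count[seq_len(n_train)]
  rows <- mm1[!is.na(mm1$demand) &
                mm1$target_date <= world$series$date[n_train], , drop = FALSE]
  attr(rows, "feature_cols") <- attr(mm1, "feature_cols")
  list(counts = counts, rows = rows)
}

test_that("all nine learners honour the fit/predict contract", {
  for (nm in learner_names()) {
    spec <- small_spec(nm)
    expect_s3_class(spec, "learner_spec")
    expect_identical(spec$family,
                     if (nm %in% c("arima", "ets", "stlm", "structts"))
                       "time_series" else "ml")
    fitted <- fit_learner(spec, spec$grid[[1]], train_data_for(spec),
                          seed = 7L)
    expect_s3_class(fitted, "fitted_learner")
    pred <- if (spec$family == "time_series")
      predict_learner(fitted, list(h = 1L))
    else
      predict_learner(fitted, mm1[mm1$target_date ==
                                    world$series$date[121], ])
    expect_length(pred, 1L)
    expect_true(is.finite(pred) && pred >= 0, label = nm)
  }
})

test_that("grids are validated and lm's grid is a single empty setting", {
  expect_error(learner_spec("nonsense"))
  expect_error(learner_spec("lm", grid = list(list(a = 1))),
               class = "demandcast_config_error")
  expect_error(learner_spec("rf", grid = list()),
               class = "demandcast_config_error")
  expect_identical(names(learner_spec("knn")$grid),
                   sprintf("hp%02d", 1:5))
})

test_that("lm reproduces an exact linear relationship in-sample", {
  rows <- train_data_for(NULL)$rows
  rows$demand <- rows$yesterday  # demand == yesterday exactly
  fitted <- fit_learner(learner_spec("lm"), list(),
                        list(rows = rows))
  pred <- predict_learner(fitted, rows)
  expect_equal(pred, as.numeric(rows$demand), tolerance = 1e-8)
})

test_that("1-NN returns the nearest training row's demand", {
  rows <- train_data_for(NULL)$rows
  fitted <- fit_learner(learner_spec("knn", grid = list(list(k = 1L))),
                        list(k = 1L), list(rows = rows))
  # query an exact training row: its own demand must come back
  pred <- predict_learner(fitted, rows[13, ])
  expect_equal(pred, as.numeric(rows$demand[13]))
})

test_that("unpenalized elastic net matches least squares", {
  rows <- train_data_for(NULL)$rows
  fit_glm <- fit_learner(
    learner_spec("glmnet", grid = list(list(mixture = 0.5, lambda = 1e-9))),
    list(mixture = 0.5, lambda = 1e-9), list(rows = rows))
  fit_lm <- fit_learner(learner_spec("lm"), list(), list(rows = rows))
  newr <- mm1[mm1$target_date %in% world$series$date[121:140], ]
  expect_equal(predict_learner(fit_glm, newr),
               predict_learner(fit_lm, newr), tolerance = 1e-3)
})

test_that("mean-reverting time-series learners forecast a constant series flat", {
  flat <- toy_series(60L, counts = rep(120L, 60L))
  for (nm in c("ets", "stlm", "structts")) {
    fitted <- fit_learner(small_spec(nm), small_grid(nm)[[1]],
                          list(counts = flat$count))
    expect_s3_class(fitted, "fitted_learner")
    for (h in c(1L, 3L, 7L))
      expect_equal(predict_learner(fitted, list(h = h)), 120,
                   tolerance = 1e-6, label = paste(nm, "h", h))
  }
})

test_that("random forest forecasts stay within the training demand range", {
  td <- train_data_for(NULL)
  fitted <- fit_learner(small_spec("rf"), small_grid("rf")[[1]], td,
                        seed = 3L)
  newr <- mm1[mm1$target_date %in% world$series$date[121:150], ]
  pred <- predict_learner(fitted, newr)
  expect_true(all(pred >= min(td$rows$demand) - 1e-9))
  expect_true(all(pred <= max(td$rows$demand) + 1e-9))
})

test_that("STL-based learner reproduces a pure weekly cycle at h = 7", {
  cycle <- rep(c(130, 150, 140, 120, 110, 90, 80), 12)
  fitted <- fit_learner(learner_spec("stlm"), list(),
                        list(counts = cycle))
  pred <- predict_learner(fitted, list(h = 7L))
  expect_equal(pred, 80, tolerance = 0.5)
  pred1 <- predict_learner(fitted, list(h = 1L))
  expect_equal(pred1, 130, tolerance = 0.5)
})

test_that("time-series learners are blind to non-demand covariates", {
  td <- train_data_for(NULL)
  td_corrupt <- td
  td_corrupt$rows$flu_prev <- rev(td_corrupt$rows$flu_prev)
  td_corrupt$rows$bank_holiday <- !td_corrupt$rows$bank_holiday
  for (nm in c("arima", "ets", "stlm", "structts")) {
    f1 <- fit_learner(small_spec(nm), small_grid(nm)[[1]], td)
    f2 <- fit_learner(small_spec(nm), small_grid(nm)[[1]], td_corrupt)
    expect_identical(predict_learner(f1, list(h = 3L)),
                     predict_learner(f2, list(h = 3L)), label = nm)
  }
})

test_that("stochastic learners are deterministic given a seed", {
  td <- train_data_for(NULL)
  newr <- mm1[mm1$target_date == world$series$date[121], ]
  for (nm in c("rf", "gbm")) {
    p <- vapply(1:2, function(i) {
      f <- fit_learner(small_spec(nm), small_grid(nm)[[1]], td, seed = 99L)
      predict_learner(f, newr)
    }, 0)
    expect_identical(p[1], p[2], label = nm)
    f3 <- fit_learner(small_spec(nm), small_grid(nm)[[1]], td, seed = 100L)
    # different seed is allowed to differ (rf will; gbm may tie)
    expect_true(is.finite(predict_learner(f3, newr)))
  }
})

test_that("degenerate training windows yield fit_failure, not a crash", {
  flat <- rep(100L, 40L)
  f <- fit_learner(small_spec("arima"),
                   list(order = c(2L, 0L, 2L), seasonal = c(1L, 0L, 1L)),
                   list(counts = flat))
  expect_true(inherits(f, c("fit_failure", "fitted_learner")))
  tiny <- list(rows = mm1[1:3, ])
  f2 <- fit_learner(learner_spec("lm"), list(), tiny)
  expect_s3_class(f2, "fit_failure")
  expect_match(f2$reason, "training rows")
  expect_error(predict_learner(f2, mm1[10, ]),
               class = "demandcast_contract_error")
})
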