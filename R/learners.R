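#' Declare a learner and its hyperparameter grid
#'
#' The framework treats nine forecasters uniformly through one fit/predict
#' contract. Four are time-series learners fitted on lagged demand only
#' (`arima`, `ets`, `stlm`, `structts`); five are machine-learning learners
#' fitted on the full model matrix (`lm`, `glmnet`, `rf`, `gbm`, `knn`).
#'
#' @param name One of `"arima"`, `"ets"`, `"stlm"`, `"structts"`, `"lm"`,
#'   `"glmnet"`, `"rf"`, `"gbm"`, `"knn"`.
#' @param grid List of hyperparameter settings (each a named list); defaults
#'   from [default_grid()]. `lm` has exactly one empty setting.
#' @return A `learner_spec` with fields `name`, `family`
#'   (`"time_series"` or `"ml"`) and `grid` (settings named `hp01`, ...).
#' @export
learner_spec <- function(name, grid = default_grid(name)) {
  name <- match.arg(name, learner_names())
  family <- if (name %in% c("arima", "ets", "stlm", "structts"))
    "time_series" else "ml"
  if (!length(grid))
    stop_demandcast("learner '%s': grid must be non-empty", name,
                    class = "demandcast_config_error")
  if (name == "lm" && (length(grid) != 1L || length(grid[[1]])))
    stop_demandcast("learner 'lm': grid must be exactly one empty setting",
                    class = "demandcast_config_error")
  names(grid) <- sprintf("hp%02d", seq_along(grid))
  structure(list(name = name, family = family, grid = grid),
            class = "learner_spec")
}

#' @rdname learner_spec
#' @export
learner_names <- function() {
  c("arima", "ets", "stlm", "structts", "lm", "glmnet", "rf", "gbm", "knn")
}

#' Default hyperparameter grids
#'
#' Conventions declared by this package (the learners' authors give none):
#' elastic net mixes `mixture` in \{0, 0.5, 1\} with 20 log-spaced penalty
#' magnitudes; random forest varies variables-per-split over
#' \{p/3, sqrt(p), p\} with 500 trees; boosting varies trees \{100, 300\},
#' depth \{1, 3\} and learning rate \{0.05, 0.1\}; k-NN varies
#' k in \{3, 5, 7, 9, 15\}; ARIMA searches three seasonal order settings;
#' the remaining time-series learners and `lm` have a single setting.
#'
#' @param name Learner name.
#' @return List of hyperparameter settings.
#' @export
default_grid <- function(name) {
  switch(match.arg(name, learner_names()),
    arima = list(
      list(order = c(1L, 1L, 1L), seasonal = c(0L, 1L, 1L)),
      list(order = c(2L, 0L, 1L), seasonal = c(1L, 0L, 1L)),
      list(order = c(1L, 0L, 0L), seasonal = c(1L, 1L, 0L))
    ),
    ets = list(list()),
    stlm = list(list()),
    structts = list(list()),
    lm = list(list()),
    glmnet = {
      lambdas <- exp(seq(log(1e-3), log(50), length.out = 20))
      g <- list()
      for (mix in c(0, 0.5, 1)) for (lam in lambdas)
        g[[length(g) + 1L]] <- list(mixture = mix, lambda = lam)
      g
    },
    rf = list(list(mtry = "third", num_trees = 500L),
              list(mtry = "sqrt", num_trees = 500L),
              list(mtry = "all", num_trees = 500L)),
    gbm = {
      g <- list()
      for (tr in c(100L, 300L)) for (dep in c(1L, 3L))
        for (lr in c(0.05, 0.1))
          g[[length(g) + 1L]] <- list(trees = tr, depth = dep,
                                      learning_rate = lr)
      g
    },
    knn = lapply(c(3L, 5L, 7L, 9L, 15L), function(k) list(k = k))
  )
}

# Complexity score for tie-breaking toward the least complex setting:
# fewest trees/neighbours, largest penalty.
complexity_score <- function(name, hp) {
  switch(name,
    glmnet = -(hp$lambda %||% 0) + 1e-6 * (hp$mixture %||% 0),
    rf = switch(hp$mtry %||% "sqrt", sqrt = 1, third = 2, all = 3) +
      (hp$num_trees %||% 500) / 1e6,
    gbm = (hp$trees %||% 100) * 100 + (hp$depth %||% 1) * 10 +
      (hp$learning_rate %||% 0.1),
    knn = hp$k %||% 5,
    0
  )
}

resolve_mtry <- function(rule, p) {
  r <- switch(as.character(rule),
              third = max(1L, floor(p / 3)),
              sqrt = max(1L, floor(sqrt(p))),
              all = p,
              as.integer(rule))
  min(max(1L, r), p)
}

#' Fit a learner on one training window
#'
#' Time-series learners consume only the demand counts of the window
#' (weekly frequency 7); machine-learning learners consume the model-matrix
#' rows. Stochastic learners (`rf`, `gbm`) are deterministic given `seed`.
#' Estimation failures (e.g. a degenerate constant window for
#' variance-requiring learners) return a `fit_failure` object carrying the
#' reason — callers record and skip them; they never crash a backtest.
#'
#' @param spec A [learner_spec()].
#' @param hyperparams One setting from `spec$grid` (or its name).
#' @param train_data List with `counts` (the training window's demand
#'   values, oldest first) for time-series learners and/or `rows`
#'   (model-matrix training rows) for ML learners.
#' @param seed Integer seed for stochastic learners.
#' @return A `fitted_learner`, or a `fit_failure` with a `reason` field.
#' @export
fit_learner <- function(spec, hyperparams = spec$grid[[1]], train_data,
                        seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  if (is.character(hyperparams)) hyperparams <- spec$grid[[hyperparams]]
  out <- tryCatch(
    fit_learner_impl(spec, hyperparams, train_data, seed),
    error = function(e) {
      structure(list(spec = spec, reason = conditionMessage(e)),
                class = "fit_failure")
    })
  out
}

#' @export
print.fit_failure <- function(x, ...) {
  cat("<fit_failure>", x$spec$name, "-", x$reason, "\n")
  invisible(x)
}

fit_learner_impl <- function(spec, hp, train_data, seed) {
  fitted <- if (spec$family == "time_series") {
    y <- train_data$counts
    if (is.null(y)) stop("time-series learner needs train_data$counts")
    yt <- ts(as.numeric(y), frequency = 7)
    fit_ts_learner(spec$name, hp, yt)
  } else {
    rows <- train_data$rows
    if (is.null(rows)) stop("ML learner needs train_data$rows")
    rows <- rows[!is.na(rows$demand), , drop = FALSE]
    if (nrow(rows) < 8L) stop("too few complete training rows")
    feature_cols <- attr(train_data$rows, "feature_cols")
    X <- ml_design(rows, feature_cols)
    fit_ml_learner(spec$name, hp, X, rows$demand, seed, feature_cols)
  }
  structure(list(spec = spec, hyperparams = hp, fit = fitted,
                 n_train = if (spec$family == "time_series")
                   length(train_data$counts) else nrow(train_data$rows),
                 seed = seed),
            class = "fitted_learner")
}

fit_ts_learner <- function(name, hp, yt) {
  switch(name,
    arima = {
      # optimizer chatter (convergence code 1) is routine on short windows
      fit <- suppressWarnings(
        arima(yt, order = hp$order %||% c(1L, 1L, 1L),
              seasonal = list(order = hp$seasonal %||% c(0L, 1L, 1L),
                              period = 7),
              method = "CSS-ML"))
      list(kind = "arima", model = fit)
    },
    ets = {
      if (var(yt) < 1e-12) list(kind = "constant", value = yt[length(yt)])
      else list(kind = "hw", model = suppressWarnings(HoltWinters(yt)))
    },
    stlm = {
      if (var(yt) < 1e-12) {
        list(kind = "constant", value = yt[length(yt)])
      } else {
        dec <- stl(yt, s.window = "periodic")
        seasonal <- dec$time.series[, "seasonal"]
        seasadj <- yt - seasonal
        core <- if (var(seasadj) < 1e-10)
          list(kind = "constant", value = as.numeric(seasadj[length(seasadj)]))
        else
          list(kind = "arima011",
               model = suppressWarnings(
                 arima(ts(as.numeric(seasadj)), order = c(0L, 1L, 1L))))
        list(kind = "stlm", core = core,
             last_cycle = as.numeric(tail(seasonal, 7)))
      }
    },
    structts = {
      if (var(yt) < 1e-12) list(kind = "constant", value = yt[length(yt)])
      else list(kind = "structts",
                model = suppressWarnings(StructTS(yt, type = "BSM")))
    })
}

fit_ml_learner <- function(name, hp, X, y, seed, feature_cols) {
  p <- ncol(X)
  base <- list(feature_cols = feature_cols, colnames = colnames(X))
  switch(name,
    lm = {
      fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
      co <- fit$coefficients
      co[is.na(co)] <- 0
      c(base, list(kind = "lm", coef = co))
    },
    glmnet = {
      fit <- glmnet::glmnet(X, y, alpha = hp$mixture %||% 0.5,
                            lambda = hp$lambda %||% 1,
                            family = "gaussian", standardize = TRUE)
      c(base, list(kind = "glmnet", model = fit,
                   lambda = hp$lambda %||% 1))
    },
    rf = {
      d <- data.frame(..y = y, X, check.names = FALSE)
      fit <- ranger::ranger(
        dependent.variable.name = "..y", data = d,
        num.trees = hp$num_trees %||% 500L,
        mtry = resolve_mtry(hp$mtry %||% "sqrt", p),
        seed = seed, num.threads = 1)
      c(base, list(kind = "rf", model = fit,
                   train_range = range(y)))
    },
    gbm = {
      fit <- xgboost::xgb.train(
        params = list(max_depth = hp$depth %||% 3L,
                      eta = hp$learning_rate %||% 0.1,
                      objective = "reg:squarederror",
                      nthread = 1L, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
        nrounds = hp$trees %||% 100L,
        verbose = 0)
      c(base, list(kind = "gbm", model = fit))
    },
    knn = {
      mu <- colMeans(X)
      sdev <- apply(X, 2, sd)
      sdev[sdev < 1e-12] <- 1
      Xs <- scale(X, center = mu, scale = sdev)
      fit <- caret::knnreg(as.data.frame(Xs), y, k = min(hp$k %||% 5, nrow(X)))
      c(base, list(kind = "knn", model = fit, center = mu, scale = sdev))
    })
}

#' Forecast from a fitted learner
#'
#' Time-series learners take a horizon `h >= 1` (days past their training
#' window); ML learners take one or more model-matrix rows. Point forecasts
#' are clamped at 0 (counts cannot be negative).
#'
#' @param fitted A `fitted_learner` from [fit_learner()].
#' @param newdata For time-series learners `list(h = <days>)` (or a bare
#'   number); for ML learners `list(row = <model_matrix rows>)` (or the rows
#'   themselves).
#' @return Numeric point forecast(s), finite and nonnegative.
#' @export
predict_learner <- function(fitted, newdata) {
  if (inherits(fitted, "fit_failure"))
    stop_demandcast("cannot predict from a fit_failure (%s)", fitted$reason,
                    class = "demandcast_contract_error")
  stopifnot(inherits(fitted, "fitted_learner"))
  if (fitted$spec$family == "time_series") {
    h <- if (is.list(newdata)) newdata$h else newdata
    if (is.null(h) || any(h < 1))
      stop_demandcast("time-series learners need a horizon h >= 1",
                      class = "demandcast_contract_error")
    pred <- predict_ts_learner(fitted$fit, max(h))[h]
  } else {
    rows <- if (is.data.frame(newdata)) newdata else newdata$row
    if (is.null(rows))
      stop_demandcast("ML learners need model-matrix rows to predict",
                      class = "demandcast_contract_error")
    pred <- predict_ml_learner(fitted$fit, rows)
  }
  pred <- as.numeric(pred)
  if (any(!is.finite(pred))) stop("non-finite forecast")
  pmax(pred, 0)
}

predict_ts_learner <- function(fit, h) {
  switch(fit$kind,
    constant = rep(fit$value, h),
    arima = as.numeric(predict(fit$model, n.ahead = h)$pred),
    hw = as.numeric(predict(fit$model, n.ahead = h)),
    stlm = {
      core <- switch(fit$core$kind,
        constant = rep(fit$core$value, h),
        arima011 = as.numeric(predict(fit$core$model, n.ahead = h)$pred))
      core + fit$last_cycle[((seq_len(h) - 1L) %% 7L) + 1L]
    },
    structts = as.numeric(predict(fit$model, n.ahead = h)$pred))
}

predict_ml_learner <- function(fit, rows) {
  X <- ml_design(rows, fit$feature_cols)
  X <- X[, fit$colnames, drop = FALSE]
  switch(fit$kind,
    lm = as.numeric(cbind(1, X) %*% fit$coef),
    glmnet = as.numeric(predict(fit$model, newx = X, s = fit$lambda)),
    rf = predict(fit$model, data = as.data.frame(X),
                 num.threads = 1)$predictions,
    gbm = predict(fit$model, newdata = X),
    knn = {
      Xs <- scale(X, center = fit$center, scale = fit$scale)
      predict(fit$model, as.data.frame(Xs))
    })
}
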