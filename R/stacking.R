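#' Fit the convex-combination stacker
#'
#' Combines K base forecasters into a single ensemble by least squares
#' under convex-combination constraints: weights are nonnegative and sum to
#' one, so the stacked forecast always lies within the range of the base
#' forecasts. Trained on cross-validation predictions (one row per date,
#' one column per learner) against the realized actuals; rows containing
#' any missing prediction are dropped and their count reported.
#'
#' The program `min ||y - P w||^2  s.t.  w >= 0, sum(w) = 1` is solved
#' exactly by enumerating the faces of the simplex: for every support
#' subset the equality-constrained least-squares KKT system is solved (via
#' a pseudoinverse, so rank-deficient faces yield the deterministic
#' minimum-norm solution), feasible candidates are scored, and the best
#' objective wins, with ties broken toward smaller support then
#' lexicographic order. Exact to machine precision for K <= `max_exact`
#' learners; beyond that a projected-gradient descent with the same
#' constraints takes over.
#'
#' @param predictions Numeric matrix or data frame, `n x K`, columns named
#'   per learner.
#' @param actuals Numeric vector of length `n`.
#' @param ridge Optional nonnegative ridge penalty on the weights (an `l2`
#'   shrinkage toward small weights, the penalized stacker variant);
#'   default 0 (pure least squares).
#' @param max_exact Largest K for which face enumeration is used
#'   (default 12).
#' @return A `stack_weights` object: named nonnegative weights summing to
#'   one, with attributes `objective` (residual sum of squares on the
#'   fitting data) and `n_dropped` (rows removed for missing predictions).
#' @export
fit_stack <- function(predictions, actuals, ridge = 0, max_exact = 12L) {
  P <- as.matrix(predictions)
  if (is.null(colnames(P)))
    colnames(P) <- paste0("learner", seq_len(ncol(P)))
  if (!nrow(P) || !ncol(P))
    stop_demandcast("empty stacking input",
                    class = "demandcast_stack_error")
  if (length(actuals) != nrow(P))
    stop_demandcast("predictions (%d rows) and actuals (%d) differ in length",
                    nrow(P), length(actuals),
                    class = "demandcast_contract_error")
  keep <- stats::complete.cases(P) & !is.na(actuals)
  n_dropped <- sum(!keep)
  P <- P[keep, , drop = FALSE]; y <- as.numeric(actuals[keep])
  if (!nrow(P))
    stop_demandcast("no complete rows to fit the stacker on",
                    class = "demandcast_stack_error")
  K <- ncol(P)
  w <- if (K == 1L) 1 else if (K <= max_exact) {
    simplex_ls_exact(P, y, ridge)
  } else {
    simplex_ls_pg(P, y, ridge)
  }
  w <- pmax(w, 0); w <- w / sum(w)
  names(w) <- colnames(P)
  structure(w, objective = sum((y - as.numeric(P %*% w))^2),
            n_dropped = n_dropped, class = "stack_weights")
}

# Exact simplex-constrained least squares by face enumeration: the global
# optimum of a convex QP over the simplex is the relative-interior optimum
# of some face, i.e. the sum-to-one equality-constrained solution on that
# support. The equality constraint is eliminated by substitution
# (w_last = 1 - sum(others)), keeping the solve well-conditioned; the
# pseudoinverse makes rank-deficient faces deterministic (minimum-norm).
simplex_ls_exact <- function(P, y, ridge = 0) {
  K <- ncol(P)
  best <- NULL
  for (mask in seq_len(2^K - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0L)
    k <- length(S)
    wS <- if (k == 1L) 1 else {
      PS <- P[, S, drop = FALSE]
      # w = Z v + e with e = unit on the last support coord,
      # Z = rbind(diag(k-1), -1)
      A <- PS[, -k, drop = FALSE] - PS[, k]
      rhs <- y - PS[, k]
      if (ridge > 0) {
        Zr <- sqrt(ridge) * rbind(diag(k - 1L), rep(-1, k - 1L))
        A <- rbind(A, Zr)
        rhs <- c(rhs, -sqrt(ridge) * c(rep(0, k - 1L), 1))
      }
      v <- as.numeric(MASS::ginv(A) %*% rhs)
      c(v, 1 - sum(v))
    }
    if (any(wS < -1e-9)) next
    wS <- pmax(wS, 0); wS <- wS / sum(wS)
    w <- numeric(K); w[S] <- wS
    obj <- sum((y - as.numeric(P %*% w))^2) + ridge * sum(w^2)
    cand <- list(w = w, obj = obj, support = k)
    if (is.null(best) || cand$obj < best$obj - 1e-12 ||
        (abs(cand$obj - best$obj) <= 1e-12 && k < best$support)) best <- cand
  }
  best$w
}

# Projected-gradient fallback for large K (simplex projection of Duchi et
# al.); fixed step 1/L with L the largest eigenvalue of the Hessian.
simplex_ls_pg <- function(P, y, ridge = 0, tol = 1e-12, max_iter = 200000L) {
  K <- ncol(P)
  G <- 2 * (crossprod(P) + diag(ridge, K))
  b <- 2 * crossprod(P, y)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  w <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    grad <- as.numeric(G %*% w) - as.numeric(b)
    w_new <- project_simplex(w - grad / L)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  w
}

project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Fit the stacker with forward-validated ridge selection
#'
#' Fits both the plain least-squares stacker and ridge-penalized variants
#' (which shrink the weights toward the uniform combination, a robust
#' choice when the fitting window is short), and picks the penalty level by
#' forward validation: weights are estimated on the chronologically first
#' part of the fitting rows and scored on the held-back remainder, then the
#' winning penalty is refitted on all rows. Penalty levels are scaled to
#' the problem (multiples of `n x` the equal-weight ensemble's mean squared
#' residual), so the choice is unit-free.
#'
#' @inheritParams fit_stack
#' @param ridge_grid Dimensionless penalty multipliers to compare
#'   (0 = plain least squares).
#' @param holdout_frac Fraction of fitting rows (chronological tail) used
#'   to score the candidates.
#' @return A `stack_weights` object with an extra attribute `ridge` (the
#'   selected penalty on the original scale).
#' @export
fit_stack_tuned <- function(predictions, actuals,
                            ridge_grid = c(0, 0.3, 1, 3, 10),
                            holdout_frac = 0.3) {
  P <- as.matrix(predictions)
  keep <- stats::complete.cases(P) & !is.na(actuals)
  P <- P[keep, , drop = FALSE]; y <- as.numeric(actuals[keep])
  n <- nrow(P)
  if (n < 10L || ncol(P) == 1L) {
    w <- fit_stack(P, y)
    attr(w, "ridge") <- 0
    return(w)
  }
  n_hold <- max(3L, ceiling(holdout_frac * n))
  fit_idx <- seq_len(n - n_hold)
  hold_idx <- seq.int(n - n_hold + 1L, n)
  scale <- n * mean((y - rowMeans(P))^2)
  hold_mse <- vapply(ridge_grid, function(r) {
    w <- fit_stack(P[fit_idx, , drop = FALSE], y[fit_idx],
                   ridge = r * scale)
    mean((y[hold_idx] - as.numeric(P[hold_idx, , drop = FALSE] %*%
                                     as.numeric(w)))^2)
  }, 0)
  # ties break toward the stronger (more regular) penalty
  chosen <- ridge_grid[rev(which(hold_mse == min(hold_mse)))[1]] * scale
  w <- fit_stack(P, y, ridge = chosen)
  attr(w, "ridge") <- chosen
  w
}

#' Stacked point forecast
#'
#' Weighted average of the base forecasts for one date. Every learner with
#' positive weight must have a prediction; the result lies within the
#' componentwise range of the inputs.
#'
#' @param weights A [fit_stack()] result (or named nonnegative weights
#'   summing to 1).
#' @param predictions Named numeric vector (or matrix with learner columns)
#'   of base forecasts.
#' @return Stacked forecast(s) in patients/day.
#' @export
predict_stack <- function(weights, predictions) {
  w <- unclass(weights)
  if (is.matrix(predictions) || is.data.frame(predictions)) {
    P <- as.matrix(predictions)[, names(w), drop = FALSE]
    need <- names(w)[w > 0]
    if (anyNA(P[, need]))
      stop_demandcast("missing prediction for a positively weighted learner",
                      class = "demandcast_contract_error")
    P[is.na(P)] <- 0
    return(as.numeric(P %*% w))
  }
  p <- predictions[names(w)]
  if (any(is.na(p[w > 0])))
    stop_demandcast("missing prediction for a positively weighted learner",
                    class = "demandcast_contract_error")
  p[is.na(p)] <- 0
  sum(w * p)
}

#' Align per-learner forecast logs into a stacking table
#'
#' Joins one or more `forecast_log`s on target date, keeping each learner's
#' successful predictions, and returns the date-aligned prediction matrix
#' plus actuals — the input shape [fit_stack()] expects.
#'
#' @param logs A list of `forecast_log`s (one per learner/configuration);
#'   names become column names (default: the learner names).
#' @return List with `dates`, `predictions` (matrix), `actuals`.
#' @export
stacking_table <- function(logs) {
  if (inherits(logs, "data.frame")) logs <- list(logs)
  if (is.null(names(logs)) || any(!nzchar(names(logs))))
    names(logs) <- vapply(logs, function(l) l$learner[1], "")
  dates <- sort(unique(as.Date(Reduce(c, lapply(logs, function(l)
    l$target_date)))))
  P <- sapply(names(logs), function(nm) {
    l <- logs[[nm]]
    ok <- l[l$status == "ok", , drop = FALSE]
    ok$prediction[match(dates, ok$target_date)]
  })
  P <- matrix(P, nrow = length(dates),
              dimnames = list(NULL, names(logs)))
  actuals <- rep(NA_real_, length(dates))
  for (l in logs) {
    i <- match(as.Date(l$target_date), dates)
    actuals[i] <- l$actual
  }
  list(dates = dates, predictions = P, actuals = actuals)
}
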