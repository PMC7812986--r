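#' Read and write demand series and covariate calendars as CSV
#'
#' CSV files with a mandatory header and ISO-8601 `date` columns. Reading
#' validates the frame: malformed dates and counts are rejected with the
#' offending line number, duplicate dates with their line numbers, and date
#' gaps with the first missing date.
#'
#' @param path File path.
#' @return `read_demand_series()`: a `demand_series`;
#'   `read_covariate_calendar()`: a `covariate_calendar`.
#' @export
read_demand_series <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "count") %in% names(raw)))
    stop_demandcast("%s: expected columns 'date' and 'count'", path,
                    class = "demandcast_parse_error")
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop_demandcast("%s: malformed date at line %d", path,
                    which(is.na(dates))[1] + 1L,
                    class = "demandcast_parse_error")
  counts <- suppressWarnings(as.numeric(raw$count))
  if (anyNA(counts) || any(counts < 0))
    stop_demandcast("%s: malformed or negative count at line %d", path,
                    which(is.na(counts) | counts < 0)[1] + 1L,
                    class = "demandcast_parse_error")
  check_consecutive(dates, path)
  out <- data.frame(date = dates, count = as.integer(round(counts)))
  class(out) <- c("demand_series", "data.frame")
  out
}

check_consecutive <- function(dates, path) {
  if (anyDuplicated(dates)) {
    d <- dates[duplicated(dates)][1]
    stop_demandcast("%s: duplicate date %s (lines %s)", path, format(d),
                    paste(which(dates == d) + 1L, collapse = ", "),
                    class = "demandcast_parse_error")
  }
  dd <- as.integer(diff(dates))
  if (length(dd) && any(dd != 1L)) {
    i <- which(dd != 1L)[1]
    if (dd[i] < 1L)
      stop_demandcast("%s: dates not in increasing order at line %d", path,
                      i + 2L, class = "demandcast_parse_error")
    stop_demandcast("%s: date gap — missing %s", path, format(dates[i] + 1L),
                    class = "demandcast_gap_error")
  }
}

#' @rdname read_demand_series
#' @param x The object to write.
#' @export
write_demand_series <- function(x, path) {
  out <- data.frame(date = format(x$date, "%Y-%m-%d"), count = x$count)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_demand_series
#' @export
read_covariate_calendar <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "bank_holiday", "school_holiday", "precipitation",
            "tmax", "tmin", "flu_hits")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_demandcast("%s: missing column '%s'", path, miss[1],
                    class = "demandcast_parse_error")
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop_demandcast("%s: malformed date at line %d", path,
                    which(is.na(dates))[1] + 1L,
                    class = "demandcast_parse_error")
  check_consecutive(dates, path)
  out <- raw
  out$date <- dates
  for (col in setdiff(names(out), c("date", "precipitation", "tmax", "tmin",
                                    "flu_hits")))
    out[[col]] <- as.logical(out[[col]])
  if (any(out$tmin > out$tmax))
    stop_demandcast("%s: tmin > tmax at line %d", path,
                    which(out$tmin > out$tmax)[1] + 1L,
                    class = "demandcast_parse_error")
  if (any(out$precipitation < 0) ||
      any(out$flu_hits < 0 | out$flu_hits > 100))
    stop_demandcast("%s: precipitation must be >= 0 and flu_hits in [0, 100]",
                    path, class = "demandcast_parse_error")
  class(out) <- c("covariate_calendar", "data.frame")
  out
}

#' @rdname read_demand_series
#' @export
write_covariate_calendar <- function(x, path) {
  out <- as.data.frame(x)
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_demand_series
#' @export
write_forecast_log <- function(x, path) {
  out <- as.data.frame(x)
  out$target_date <- format(out$target_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_demand_series
#' @export
read_forecast_log <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$target_date <- as.Date(raw$target_date)
  class(raw) <- c("forecast_log", "data.frame")
  raw
}

#' @rdname read_demand_series
#' @export
write_model_matrix <- function(x, path) {
  out <- as.data.frame(x)
  out$target_date <- format(out$target_date, "%Y-%m-%d")
  out$origin_date <- format(out$origin_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' A single declarative YAML file drives an end-to-end run: input paths (or
#' a synthetic block), horizons, block lengths, learners and grids, tuning
#' method/rule/periods, stacking options and the global seed. Unknown
#' learner names and horizons outside \{1, 3, 7\} are rejected at parse
#' time.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A config list (as from YAML).
#' @export
validate_run_config <- function(config) {
  defaults <- list(
    horizons = 1L, train_length = 120L, val_length = 60L,
    test_length = 30L, seed = 1L,
    learners = list(lm = NULL, glmnet = NULL),
    tuning = list(method = "batch", rules = selection_rule_kinds(),
                  n = 7L, alpha = 0.1, periods = c(1L, 7L, 30L)),
    stacking = list(enabled = TRUE, ridge = "auto"),
    importance = list(enabled = TRUE, repeats = 10L, learner = "lm"),
    output_dir = "demandcast-output"
  )
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  # the learner list is a selection, not a set of overrides
  if (!is.null(config$learners)) cfg$learners <- config$learners
  cfg$horizons <- as.integer(cfg$horizons)
  if (!all(cfg$horizons %in% c(1L, 3L, 7L)))
    stop_demandcast("config: horizons must be a subset of {1, 3, 7}",
                    class = "demandcast_config_error")
  bad <- setdiff(names(cfg$learners), learner_names())
  if (length(bad))
    stop_demandcast("config: unknown learner '%s'", bad[1],
                    class = "demandcast_config_error")
  if (!is.null(cfg$tuning$method) &&
      !cfg$tuning$method %in% c("batch", "online"))
    stop_demandcast("config: tuning method must be 'batch' or 'online'",
                    class = "demandcast_config_error")
  bad_rule <- setdiff(cfg$tuning$rules, selection_rule_kinds())
  if (length(bad_rule))
    stop_demandcast("config: unknown selection rule '%s'", bad_rule[1],
                    class = "demandcast_config_error")
  structure(cfg, class = c("run_config", "list"))
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config), control = "all"), collapse = "")
  # order-stable 31-bit FNV-1a-style hash over the deparsed config
  h <- 2166136261 %% 2147483648
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", h)
}
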