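# Shared time arithmetic and small statistics used across the pipeline.
# All timestamps are integer milliseconds since the Unix epoch in one fixed
# timezone (UTC); days and weeks are calendar-aligned in that zone.

MS_PER_SEC <- 1000
MS_PER_HOUR <- 3600 * MS_PER_SEC
MS_PER_DAY <- 24 * MS_PER_HOUR
MS_PER_WEEK <- 7 * MS_PER_DAY
# 1970-01-01 was a Thursday; the first Monday of the epoch is day 4
EPOCH_MONDAY_OFFSET_DAYS <- 4

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())
    ), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Convert a calendar date to milliseconds since epoch (UTC midnight)
#' @param date a `Date` or string coercible to one.
#' @return numeric milliseconds.
#' @keywords internal
date_to_ms <- function(date) {
  as.numeric(as.Date(date)) * MS_PER_DAY
}

#' @keywords internal
ms_to_date <- function(ms) {
  as.Date(floor(ms / MS_PER_DAY), origin = "1970-01-01")
}

# Day index since epoch, hour of day, Monday-based day of week
day_index <- function(ts_ms) floor(ts_ms / MS_PER_DAY)
hour_of_day_of <- function(ts_ms) floor(ts_ms / MS_PER_HOUR) %% 24
dow_monday <- function(ts_ms) {
  (day_index(ts_ms) - EPOCH_MONDAY_OFFSET_DAYS) %% 7
}

#' Start of the Monday-aligned week containing a timestamp
#' @param ts_ms milliseconds since epoch.
#' @return milliseconds of the Monday midnight starting the week.
#' @keywords internal
monday_week_start_ms <- function(ts_ms) {
  d <- day_index(ts_ms)
  wk <- floor((d - EPOCH_MONDAY_OFFSET_DAYS) / 7)
  (EPOCH_MONDAY_OFFSET_DAYS + 7 * wk) * MS_PER_DAY
}

# 6-hour period of day: 0 = midnight-6AM, 1 = 6AM-noon, 2 = noon-6PM,
# 3 = 6PM-midnight
six_hour_period_of <- function(ts_ms) {
  floor(ts_ms / (6 * MS_PER_HOUR)) %% 4
}

#' Population standard deviation (divisor n)
#'
#' The variability features use the population convention; `NA` on empty
#' input, 0 on singletons and constant series.
#'
#' @param x numeric vector.
#' @return scalar.
#' @export
#' @examples
#' pop_sd(c(10, 20, 30)) # 8.1649...
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Percentile-range dispersion (MaxGap)
#'
#' The difference between the 95th and 5th percentiles of a series, using
#' linear interpolation between order statistics (position `1 + q * (n - 1)`,
#' i.e. the classical type-7 definition). Captures the maximal fluctuation of
#' a feature within a time window while being robust to single outliers.
#'
#' @param values numeric vector of feature values.
#' @param probs the two probabilities; default `c(0.05, 0.95)`.
#' @return non-negative scalar; `NA` on empty input.
#' @export
#' @examples
#' max_gap(1:100) # 89.1
#' max_gap(rep(5, 4)) # 0
max_gap <- function(values, probs = c(0.05, 0.95)) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  q <- stats::quantile(values, probs = probs, type = 7, names = FALSE)
  q[2] - q[1]
}
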