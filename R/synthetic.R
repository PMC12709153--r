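# Seeded synthetic keystroke-log generator.
#
# Emulates the structure of free-living smartphone typing logs: per-hour
# session arrivals following a diurnal activity profile, log-normal
# inter-press and hold latencies whose medians are age-graded (older users
# type more slowly and less often), delete and layout-shift keys, occasional
# long-hold and burst artifacts, and occasionally missing weeks. Every
# downstream stage of the pipeline is testable against these logs.

AGE_GROUP_LEVELS <- c("<30", "30s", "40s", "50s")

#' Age-group label for an age in years
#' @param age integer vector of ages.
#' @return factor with levels `<30`, `30s`, `40s`, `50s`.
#' @export
age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 29, 39, 49, Inf), labels = AGE_GROUP_LEVELS)
}

#' Configuration for the synthetic keystroke generator
#'
#' Defaults encode the study conditions the generator emulates: four decade
#' age groups; typing speed (median inter-press latency around 0.2 s for
#' people in their twenties, rising with age) and hold time both increasing
#' with age; daily typing volume decreasing with age; a late-evening activity
#' peak for younger users that fades by the mid-forties; a burst-artifact
#' rate sized so a few percent of sessions are discarded by the burst filter.
#'
#' @param n_per_group named integer vector of participants per age group.
#' @param n_weeks number of weeks of data per participant (>= 2; the first
#'   week is discarded by preprocessing).
#' @param seed integer master seed.
#' @param start_date enrollment date for all participants (a Monday keeps
#'   calendar weeks complete).
#' @param ppl_intercept,ppl_slope,ppl_sd linear map age -> median
#'   press-to-press latency in ms, with inter-participant Gaussian spread.
#' @param hold_intercept,hold_slope,hold_sd same for the median hold time.
#' @param budget_intercept,budget_slope,budget_sd,budget_min linear map
#'   age -> expected key presses per day (decreasing), floored.
#' @param mean_session_keys expected keystrokes per typing session.
#' @param ppl_sdlog,hold_sdlog log-normal shape of within-person latencies.
#' @param delete_prob,shift_prob per-key probability of a delete /
#'   layout-shift key.
#' @param missing_week_prob probability a whole week is emitted empty.
#' @param long_hold_prob per-key probability of an artifact hold > 5 s.
#' @param burst_session_prob probability a session is an input-artifact
#'   burst (>= 10 keystrokes inside 1 s), so that the burst filter discards
#'   a realistic few percent of sessions.
#' @param evening_peak_max_age age below which the late-evening (11 PM)
#'   activity peak is present, linearly fading to zero at this age.
#' @param emit_markers emit explicit `KB_OPEN`/`KB_CLOSE` keyboard
#'   activation markers around each session; when `FALSE` the sessionizer
#'   must rely on the idle-gap rule alone.
#' @return a `keydyn_generator_config` list.
#' @export
generator_config <- function(n_per_group = c("<30" = 14, "30s" = 14,
                                             "40s" = 14, "50s" = 14),
                             n_weeks = 8,
                             seed = 1L,
                             start_date = as.Date("2023-01-02"),
                             ppl_intercept = 145, ppl_slope = 2.8,
                             ppl_sd = 10,
                             hold_intercept = 62, hold_slope = 1.0,
                             hold_sd = 6,
                             budget_intercept = 1250, budget_slope = -16,
                             budget_sd = 60, budget_min = 150,
                             mean_session_keys = 22,
                             ppl_sdlog = 0.35, hold_sdlog = 0.30,
                             delete_prob = 0.08, shift_prob = 0.04,
                             missing_week_prob = 0.05,
                             long_hold_prob = 2e-4,
                             burst_session_prob = 0.034,
                             evening_peak_max_age = 45,
                             emit_markers = TRUE) {
  n_per_group <- n_per_group[AGE_GROUP_LEVELS]
  names(n_per_group) <- AGE_GROUP_LEVELS
  if (anyNA(n_per_group) || any(n_per_group < 1)) {
    stop("`n_per_group` must give a positive count for each of ",
         paste(AGE_GROUP_LEVELS, collapse = ", "))
  }
  if (n_weeks < 2) stop("`n_weeks` must be >= 2 (week 1 is discarded)")
  rates <- c(delete_prob, shift_prob, missing_week_prob, long_hold_prob,
             burst_session_prob)
  if (any(rates < 0 | rates > 1)) stop("all probabilities must lie in [0, 1]")
  structure(as.list(environment()), class = "keydyn_generator_config")
}

# Hourly activity template: quiet small hours, daytime plateau, evening
# bump; younger users add a late-night peak at 11 PM.
.diurnal_base <- c(0.5, 0.3, 0.2, 0.2, 0.3, 0.5,
                   1.0, 1.8, 2.5, 2.8, 2.8, 2.8,
                   3.0, 2.8, 2.8, 2.8, 2.8, 3.0,
                   3.2, 3.4, 3.4, 3.2, 2.8, 2.0)
.diurnal_evening <- c(rep(0, 20), 0.5, 1.2, 2.2, 3.0)

.diurnal_weights <- function(age, max_age, jitter_sdlog = 0.10) {
  young <- max(0, (max_age - age) / (max_age - 20))
  w <- .diurnal_base + young * .diurnal_evening
  w <- w * rlnorm(24, 0, jitter_sdlog)
  w / sum(w)
}

#' Generate a synthetic participant cohort
#'
#' Draws one profile per participant: uniform integer age within the group's
#' range, sex, and age-graded generator parameters (latency medians, daily
#' key budget, diurnal activity weights).
#'
#' @param config a [generator_config()].
#' @return `data.table` with one row per participant: `participant_id`,
#'   `age`, `age_group`, `sex`, `enrollment_date`, `base_hold_ms`,
#'   `base_ppl_ms`, `daily_key_budget`, `delete_prob`, `shift_prob`,
#'   `missing_week_prob`, and list-column `diurnal_weights` (24 shares
#'   summing to 1).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "keydyn_generator_config"))
  ranges <- list("<30" = 19:29, "30s" = 30:39, "40s" = 40:49, "50s" = 50:59)
  with_seed(config$seed, {
    ages <- unlist(lapply(AGE_GROUP_LEVELS, function(g) {
      sample(ranges[[g]], config$n_per_group[[g]], replace = TRUE)
    }))
    n <- length(ages)
    dt <- data.table(
      participant_id = sprintf("P%03d", seq_len(n)),
      age = as.integer(ages),
      age_group = age_group_of(ages),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.65, 0.35)),
      enrollment_date = as.Date(config$start_date),
      base_hold_ms = pmax(30, config$hold_intercept +
                            config$hold_slope * ages + rnorm(n, 0, config$hold_sd)),
      base_ppl_ms = pmax(80, config$ppl_intercept +
                           config$ppl_slope * ages + rnorm(n, 0, config$ppl_sd)),
      daily_key_budget = pmax(config$budget_min, config$budget_intercept +
                                config$budget_slope * ages +
                                rnorm(n, 0, config$budget_sd)),
      delete_prob = config$delete_prob,
      shift_prob = config$shift_prob,
      missing_week_prob = config$missing_week_prob
    )
    dt[, diurnal_weights := lapply(age, .diurnal_weights,
                                   max_age = config$evening_peak_max_age)]
    dt[]
  })
}

#' Generate a keystroke log for one participant
#'
#' Sessions arrive per day following the participant's diurnal weights;
#' within a session, successive press times advance by log-normal
#' inter-press latencies with median `base_ppl_ms` and holds with median
#' `base_hold_ms`. Delete and layout-shift keys, long-hold artifacts, burst
#' sessions and missing weeks are injected at the configured rates.
#'
#' @param profile one row of [generate_cohort()] (a list or one-row
#'   data.table).
#' @param n_weeks number of weeks to simulate (>= 1).
#' @param seed integer seed; the log is a deterministic function of
#'   (profile, n_weeks, seed).
#' @param config the [generator_config()] supplying artifact rates and
#'   latency shapes.
#' @return `data.table` of key events ordered by press time: `press_ts`,
#'   `release_ts` (ms since epoch, UTC), `key_class` in
#'   `{char, delete, layout_shift, KB_OPEN, KB_CLOSE}`, `participant_id`.
#' @export
generate_log <- function(profile, n_weeks, seed, config = generator_config()) {
  stopifnot(n_weeks >= 1)
  if (is.data.table(profile)) profile <- as.list(profile[1])
  dw <- profile$diurnal_weights
  if (is.list(dw)) dw <- dw[[1]]
  t0 <- date_to_ms(profile$enrollment_date)

  with_seed(seed, {
    missing_week <- rbinom(n_weeks, 1, profile$missing_week_prob) == 1
    mean_sessions_day <- profile$daily_key_budget / config$mean_session_keys

    out <- vector("list", n_weeks * 7)
    for (d in seq_len(n_weeks * 7) - 1L) {
      if (missing_week[d %/% 7 + 1L]) next
      n_sess <- rpois(1, mean_sessions_day)
      if (n_sess == 0L) next
      hrs <- sample(0:23, n_sess, replace = TRUE, prob = dw)
      starts <- sort(t0 + d * MS_PER_DAY + hrs * MS_PER_HOUR +
                       floor(runif(n_sess, 0, MS_PER_HOUR)))
      burst <- runif(n_sess) < config$burst_session_prob
      n_keys <- 1L + rpois(n_sess, config$mean_session_keys - 1)
      n_keys[burst] <- pmax(n_keys[burst], 12L)

      sess <- vector("list", n_sess)
      prev_end <- -Inf
      for (s in seq_len(n_sess)) {
        nk <- n_keys[s]
        st <- max(starts[s], prev_end + 10 * MS_PER_SEC)
        gaps <- if (burst[s]) {
          runif(nk - 1, 55, 95)
        } else {
          rlnorm(nk - 1, log(profile$base_ppl_ms), config$ppl_sdlog)
        }
        press <- st + c(0, cumsum(gaps))
        holds <- rlnorm(nk, log(profile$base_hold_ms), config$hold_sdlog)
        long <- runif(nk) < config$long_hold_prob
        holds[long] <- runif(sum(long), 5001, 15000)
        cls <- sample(c("delete", "layout_shift", "char"), nk, replace = TRUE,
                      prob = c(profile$delete_prob, profile$shift_prob,
                               1 - profile$delete_prob - profile$shift_prob))
        ev <- data.table(press_ts = round(press),
                         release_ts = round(press + holds),
                         key_class = cls)
        if (config$emit_markers) {
          ev <- rbind(
            data.table(press_ts = ev$press_ts[1] - 200,
                       release_ts = ev$press_ts[1] - 200,
                       key_class = "KB_OPEN"),
            ev,
            data.table(press_ts = max(ev$release_ts) + 200,
                       release_ts = max(ev$release_ts) + 200,
                       key_class = "KB_CLOSE"))
        }
        prev_end <- max(ev$release_ts)
        sess[[s]] <- ev
      }
      out[[d + 1L]] <- rbindlist(sess)
    }
    events <- rbindlist(out)
    if (nrow(events) == 0L) {
      events <- data.table(press_ts = numeric(), release_ts = numeric(),
                           key_class = character())
    }
    setorder(events, press_ts, release_ts)
    events[, participant_id := profile$participant_id]
    events[]
  })
}

#' Write a keystroke log to the tab-separated interchange format
#'
#' Columns `press_ts_ms`, `release_ts_ms`, `key_class`, one row per key
#' event; keyboard activation markers use key classes `KB_OPEN`/`KB_CLOSE`
#' with equal press and release timestamps. Round-trips through
#' [parse_log()].
#'
#' @param events event `data.table` from [generate_log()].
#' @param path output file path (conventionally `<participant_id>.tsv`).
#' @return `path`, invisibly.
#' @export
write_log <- function(events, path) {
  out <- data.table(press_ts_ms = format(events$press_ts, scientific = FALSE,
                                         trim = TRUE),
                    release_ts_ms = format(events$release_ts,
                                           scientific = FALSE, trim = TRUE),
                    key_class = events$key_class)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write / read the cohort manifest
#'
#' CSV with columns `participant_id,age,sex,enrollment_date`.
#'
#' @param cohort a [generate_cohort()] table.
#' @param path CSV path.
#' @return `path` invisibly (`write_cohort`); manifest `data.table`
#'   (`read_cohort`).
#' @export
write_cohort <- function(cohort, path) {
  fwrite(cohort[, .(participant_id, age, sex, enrollment_date)], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  m <- fread(path, colClasses = list(character = "participant_id"))
  m[, enrollment_date := as.Date(enrollment_date)]
  m[, age_group := age_group_of(age)]
  m[]
}
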