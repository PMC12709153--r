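# The 43 keystroke-dynamics features: 11 speed, 4 frequency, and their
# temporal-variability companions (22 speed-variability, 6
# frequency-variability). Speed features are medians of per-event or
# per-session series pooled within a time window; frequency features are
# counts; {f}_MaxGap and {f}_STD summarize the fluctuation of hourly
# sub-window summaries inside the window.

SPEED_FEATURES <- c("HT", "FT", "PPL", "RRL", "precorrection", "correction",
                    "postcorrection", "AllKeyRate", "DELRate", "dur_shift",
                    "dur_session")
FREQUENCY_FEATURES <- c("AllKey", "DEL", "num_shift", "num_session")
# num_session has no variability companion
VAR_FREQ_BASE <- c("AllKey", "DEL", "num_shift")

#' The keystroke feature inventory
#'
#' All 43 features with their category: 11 speed, 4 frequency, 22 speed
#' variability, 6 frequency variability. Speed features are in seconds
#' (latencies/durations) or per-second rates; frequency features are
#' non-negative counts.
#'
#' @param categories optional subset of
#'   `c("speed", "frequency", "speed_variability", "frequency_variability")`.
#' @return `data.table` with columns `feature`, `category`.
#' @export
keystroke_features <- function(categories = NULL) {
  cat <- data.table(
    feature = c(SPEED_FEATURES, FREQUENCY_FEATURES,
                paste0(SPEED_FEATURES, "_MaxGap"),
                paste0(SPEED_FEATURES, "_STD"),
                paste0(VAR_FREQ_BASE, "_MaxGap"),
                paste0(VAR_FREQ_BASE, "_STD")),
    category = rep(c("speed", "frequency", "speed_variability",
                     "frequency_variability"),
                   times = c(11L, 4L, 22L, 6L)))
  if (!is.null(categories)) {
    bad <- setdiff(categories, unique(cat$category))
    if (length(bad)) stop("unknown feature categories: ",
                          paste(bad, collapse = ", "))
    cat <- cat[category %in% categories]
  }
  cat[]
}

#' Per-event speed series of one typing session
#'
#' Hold time (HT) per key; flight time (FT), press-to-press (PPL) and
#' release-to-release (RRL) latencies per consecutive pair; precorrection /
#' correction / postcorrection = the flight time into, the hold time of,
#' and the flight time after a delete key; dur_shift = time from a
#' layout-shift key's press to the next key's press. All in seconds. FT
#' (and hence pre/postcorrection) may be negative under rollover typing.
#'
#' @param session event `data.table` of one session, sorted by press time,
#'   markers removed.
#' @return named list of numeric vectors (possibly empty), one per
#'   event-level speed feature.
#' @export
event_speed_series <- function(session) {
  stopifnot(nrow(session) >= 1L)
  p <- session$press_ts
  r <- session$release_ts
  cls <- session$key_class
  n <- length(p)
  ht <- (r - p) / MS_PER_SEC
  ft <- ppl <- rrl <- numeric(0)
  if (n >= 2L) {
    ft <- (p[-1] - r[-n]) / MS_PER_SEC
    ppl <- diff(p) / MS_PER_SEC
    rrl <- diff(r) / MS_PER_SEC
  }
  is_del <- cls == "delete"
  shift_idx <- which(cls == "layout_shift")
  shift_idx <- shift_idx[shift_idx < n]
  list(
    HT = ht,
    FT = ft,
    PPL = ppl,
    RRL = rrl,
    precorrection = ft[is_del[-1]],
    correction = ht[is_del],
    postcorrection = ft[is_del[-n]],
    dur_shift = (p[shift_idx + 1L] - p[shift_idx]) / MS_PER_SEC
  )
}

#' Session-level scalar speed features
#'
#' `AllKeyRate` and `DELRate` are key presses (all / delete) per second of
#' session; `dur_session` is the session duration in seconds. Rates are
#' undefined (`NA`) for a zero-duration session.
#'
#' @param session event `data.table` of one session.
#' @return named list: `AllKeyRate`, `DELRate`, `dur_session`.
#' @export
session_scalars <- function(session) {
  stopifnot(nrow(session) >= 1L)
  dur <- (max(session$release_ts) - session$press_ts[1]) / MS_PER_SEC
  if (dur > 0) {
    list(AllKeyRate = nrow(session) / dur,
         DELRate = sum(session$key_class == "delete") / dur,
         dur_session = dur)
  } else {
    list(AllKeyRate = NA_real_, DELRate = NA_real_, dur_session = dur)
  }
}

# Long table of every speed-feature value with the session's start
# timestamp attached (window assignment is by session start; sessions are
# never split across windows).
values_long <- function(pre) {
  ev <- copy(pre$events)
  if (nrow(ev) == 0L) {
    return(data.table(participant_id = character(), session_start = numeric(),
                      feature = character(), value = numeric()))
  }
  ev[, `:=`(
    ht = (release_ts - press_ts) / MS_PER_SEC,
    ft = (press_ts - data.table::shift(release_ts)) / MS_PER_SEC,
    ppl = (press_ts - data.table::shift(press_ts)) / MS_PER_SEC,
    rrl = (release_ts - data.table::shift(release_ts)) / MS_PER_SEC,
    prev_class = data.table::shift(key_class),
    next_press = data.table::shift(press_ts, type = "lead")
  ), by = .(participant_id, session_idx)]
  ev[pre$sessions, session_start := i.start_ts,
     on = c("participant_id", "session_idx")]

  take <- function(d, feat, col) {
    data.table(participant_id = d$participant_id,
               session_start = d$session_start,
               feature = feat, value = d[[col]])
  }
  parts <- list(
    take(ev, "HT", "ht"),
    take(ev[!is.na(ft)], "FT", "ft"),
    take(ev[!is.na(ppl)], "PPL", "ppl"),
    take(ev[!is.na(rrl)], "RRL", "rrl"),
    take(ev[key_class == "delete" & !is.na(ft)], "precorrection", "ft"),
    take(ev[key_class == "delete"], "correction", "ht"),
    take(ev[prev_class %in% "delete" & !is.na(ft)], "postcorrection", "ft"),
    {
      sh <- ev[key_class == "layout_shift" & !is.na(next_press)]
      data.table(participant_id = sh$participant_id,
                 session_start = sh$session_start,
                 feature = "dur_shift",
                 value = (sh$next_press - sh$press_ts) / MS_PER_SEC)
    },
    # per-session scalars
    {
      sc <- session_count_table(pre)
      rbind(
        data.table(participant_id = sc$participant_id,
                   session_start = sc$session_start,
                   feature = "AllKeyRate",
                   value = ifelse(sc$dur_session > 0,
                                  sc$AllKey / sc$dur_session, NA_real_)),
        data.table(participant_id = sc$participant_id,
                   session_start = sc$session_start,
                   feature = "DELRate",
                   value = ifelse(sc$dur_session > 0,
                                  sc$DEL / sc$dur_session, NA_real_)),
        data.table(participant_id = sc$participant_id,
                   session_start = sc$session_start,
                   feature = "dur_session", value = sc$dur_session))
    }
  )
  out <- rbindlist(parts)
  out[!is.na(value)]
}

# One row per kept session with its start and the per-session key counts.
session_count_table <- function(pre) {
  ev <- pre$events
  cnt <- ev[, .(AllKey = .N,
                DEL = sum(key_class == "delete"),
                num_shift = sum(key_class == "layout_shift")),
            by = .(participant_id, session_idx)]
  out <- pre$sessions[cnt, on = c("participant_id", "session_idx")]
  setnames(out, "start_ts", "session_start")
  out
}

#' Frequency counts in a time window
#'
#' Counts over the sessions whose start timestamp falls in
#' `[window_start, window_end)`: total key presses, delete presses,
#' layout-shift presses, and number of sessions.
#'
#' @param pre preprocessed data from [preprocess_events()].
#' @param window_start,window_end window bounds in ms since epoch.
#' @return named list `AllKey`, `DEL`, `num_shift`, `num_session`.
#' @export
window_frequency <- function(pre, window_start, window_end) {
  sc <- session_count_table(pre)
  w <- sc[session_start >= window_start & session_start < window_end]
  list(AllKey = sum(w$AllKey), DEL = sum(w$DEL),
       num_shift = sum(w$num_shift), num_session = nrow(w))
}

# Floor timestamps to the start of their window at a given resolution.
floor_window <- function(ts_ms, resolution) {
  switch(resolution,
         week = monday_week_start_ms(ts_ms),
         day = day_index(ts_ms) * MS_PER_DAY,
         six_hour = floor(ts_ms / (6 * MS_PER_HOUR)) * 6 * MS_PER_HOUR,
         hour = floor(ts_ms / MS_PER_HOUR) * MS_PER_HOUR,
         stop("unknown resolution: ", resolution))
}

#' Extract the 43 features per (participant, time window)
#'
#' Speed features are medians of the pooled per-event / per-session series
#' of all sessions starting in the window; frequency features are counts.
#' Variability companions (`_MaxGap`, [max_gap()] of 95th minus 5th
#' percentile; `_STD`, population SD) are computed over sub-window summaries
#' inside the window — per-sub-window medians for speed features, counts
#' for frequency features, both over sub-windows with activity. Windows with
#' no sessions are absent from the output; features with no values in an
#' observed window are `NA` (imputed downstream).
#'
#' @param pre preprocessed data from [preprocess_events()] (any number of
#'   participants).
#' @param resolution window granularity: `"week"` (Monday-aligned),
#'   `"day"`, `"six_hour"`, or `"hour"`.
#' @param sub_resolution granularity of the variability sub-windows
#'   (default `"hour"`); must be finer than `resolution`.
#' @return long `data.table`: `participant_id`, `window_start` (ms),
#'   `window_label`, `feature`, `value` — exactly 43 rows per observed
#'   (participant, window).
#' @export
extract_features <- function(pre, resolution = c("week", "day", "six_hour",
                                                 "hour"),
                             sub_resolution = "hour") {
  resolution <- match.arg(resolution)
  res_ms <- c(week = MS_PER_WEEK, day = MS_PER_DAY,
              six_hour = 6 * MS_PER_HOUR, hour = MS_PER_HOUR)
  if (res_ms[[sub_resolution]] > res_ms[[resolution]]) {
    stop("`sub_resolution` must not be coarser than `resolution`")
  }
  vals <- values_long(pre)
  empty <- data.table(participant_id = character(), window_start = numeric(),
                      window_label = character(), feature = character(),
                      value = numeric())
  if (nrow(vals) == 0L) return(empty)
  vals[, window_start := floor_window(session_start, resolution)]
  vals[, subwindow := floor_window(session_start, sub_resolution)]

  speed_med <- vals[, .(value = median(value)),
                    by = .(participant_id, window_start, feature)]
  sub_med <- vals[, .(med = median(value)),
                  by = .(participant_id, window_start, feature, subwindow)]
  speed_var <- sub_med[, .(MaxGap = max_gap(med), STD = pop_sd(med)),
                       by = .(participant_id, window_start, feature)]
  speed_var <- melt(speed_var, id.vars = c("participant_id", "window_start",
                                           "feature"),
                    variable.name = "stat", value.name = "value")
  speed_var[, feature := paste0(feature, "_", stat)][, stat := NULL]

  # frequency: per-session counts summed over windows / sub-windows
  sc <- session_count_table(pre)
  sc[, window_start := floor_window(session_start, resolution)]
  sc[, subwindow := floor_window(session_start, sub_resolution)]
  freq_counts <- sc[, .(AllKey = sum(AllKey), DEL = sum(DEL),
                        num_shift = sum(num_shift), num_session = .N),
                    by = .(participant_id, window_start)]
  freq_long <- melt(freq_counts, id.vars = c("participant_id",
                                             "window_start"),
                    variable.name = "feature", value.name = "value")
  freq_long[, feature := as.character(feature)]
  freq_long[, value := as.numeric(value)]

  # sub-window counts over sub-windows with typing activity; idle
  # sub-windows are absent rather than zero, mirroring the speed features
  sub_counts <- sc[, .(AllKey = sum(AllKey), DEL = sum(DEL),
                       num_shift = sum(num_shift)),
                   by = .(participant_id, window_start, subwindow)]
  sub_long <- melt(sub_counts, id.vars = c("participant_id", "window_start",
                                           "subwindow"),
                   variable.name = "feature", value.name = "value")
  freq_var <- sub_long[, .(MaxGap = max_gap(value), STD = pop_sd(value)),
                       by = .(participant_id, window_start, feature)]
  freq_var <- melt(freq_var, id.vars = c("participant_id", "window_start",
                                         "feature"),
                   variable.name = "stat", value.name = "value")
  freq_var[, feature := paste0(feature, "_", stat)][, stat := NULL]

  long <- rbindlist(list(speed_med, speed_var, freq_long, freq_var),
                    use.names = TRUE)
  # complete to exactly 43 features per observed (participant, window)
  windows <- unique(long[, .(participant_id, window_start)])
  full <- windows[, .(feature = keystroke_features()$feature),
                  by = .(participant_id, window_start)]
  out <- long[full, on = c("participant_id", "window_start", "feature")]
  out[, window_label := resolution]
  setcolorder(out, c("participant_id", "window_start", "window_label",
                     "feature", "value"))
  setorder(out, participant_id, window_start, feature)
  out[]
}
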