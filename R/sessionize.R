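# Log parsing and preprocessing: first-week discard, long-hold filter,
# session segmentation (keyboard activation markers and/or idle gap),
# burst-session exclusion.

#' Preprocessing thresholds
#'
#' The defaults are the study rules: key events held longer than 5 seconds
#' are artifacts; a pause of more than 8 seconds after the last key release
#' ends a typing session; a session containing 10 consecutive keystrokes
#' within 1 second is an input-artifact burst and is discarded. Both the 8-s
#' and 5-s thresholds are strict inequalities.
#'
#' @param max_hold_ms holds strictly longer than this are dropped.
#' @param gap_ms idle gaps strictly longer than this split sessions.
#' @param burst_k,burst_window_ms a session is discarded iff some run of
#'   `burst_k` consecutive presses spans at most `burst_window_ms`.
#' @param adaptation_days leading days discarded per participant
#'   (the first, keyboard-adaptation week).
#' @return a `keydyn_session_config` list.
#' @export
session_config <- function(max_hold_ms = 5000, gap_ms = 8000,
                           burst_k = 10L, burst_window_ms = 1000,
                           adaptation_days = 7L) {
  stopifnot(max_hold_ms > 0, gap_ms > 0, burst_k >= 2, burst_window_ms > 0)
  structure(list(max_hold_ms = max_hold_ms, gap_ms = gap_ms,
                 burst_k = as.integer(burst_k),
                 burst_window_ms = burst_window_ms,
                 adaptation_days = as.integer(adaptation_days)),
            class = "keydyn_session_config")
}

#' Parse a keystroke log file
#'
#' Reads the tab-separated log dialect (`press_ts_ms`, `release_ts_ms`,
#' `key_class`). Rows that are malformed — non-numeric timestamps or a
#' release before the press — are dropped with a warning giving the count.
#' Events are returned sorted by press timestamp.
#'
#' @param path log file path.
#' @param participant_id id attached to the events; defaults to the file
#'   name without extension.
#' @return event `data.table` (`press_ts`, `release_ts`, `key_class`,
#'   `participant_id`), possibly empty.
#' @export
parse_log <- function(path,
                      participant_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("log file not found: ", path)
  raw <- fread(path, sep = "\t", header = TRUE,
               colClasses = list(character = 1:3), fill = TRUE)
  empty <- data.table(press_ts = numeric(), release_ts = numeric(),
                      key_class = character(),
                      participant_id = character())
  if (nrow(raw) == 0L) return(empty)
  press <- suppressWarnings(as.numeric(raw[[1]]))
  release <- suppressWarnings(as.numeric(raw[[2]]))
  cls <- raw[[3]]
  ok <- !is.na(press) & !is.na(release) & !is.na(cls) & nzchar(cls) &
    release >= press
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning(sprintf("parse_log: dropped %d malformed row(s) in %s",
                    n_bad, path))
  }
  ev <- data.table(press_ts = press[ok], release_ts = release[ok],
                   key_class = cls[ok], participant_id = participant_id)
  setorder(ev, press_ts, release_ts)
  ev[]
}

#' Discard the adaptation week
#'
#' Removes all events earlier than 7 calendar days after the participant's
#' enrollment midnight; an event falling exactly on the boundary is kept
#' (half-open interval).
#'
#' @param events event `data.table`.
#' @param enrollment_date the participant's enrollment date.
#' @param days number of adaptation days (default 7).
#' @return filtered events.
#' @export
drop_adaptation_week <- function(events, enrollment_date, days = 7L) {
  cutoff <- date_to_ms(enrollment_date) + days * MS_PER_DAY
  events[press_ts >= cutoff]
}

#' Remove long-hold artifact events
#'
#' Drops key events whose press-to-release duration is strictly longer than
#' the threshold (default 5 s); marker rows are untouched.
#'
#' @param events event `data.table`.
#' @param max_hold_ms threshold in ms.
#' @return filtered events.
#' @export
filter_long_holds <- function(events, max_hold_ms = 5000) {
  events[key_class %in% c("KB_OPEN", "KB_CLOSE") |
           (release_ts - press_ts) <= max_hold_ms]
}

#' Segment events into typing sessions
#'
#' A new session starts at a keyboard-activation marker (`KB_OPEN`), after a
#' deactivation marker (`KB_CLOSE`), or — independently of markers — when
#' the next press comes more than `gap_ms` (default 8 s, strict) after the
#' last key release. Markers never appear inside the returned sessions;
#' every non-marker event belongs to exactly one session.
#'
#' @param events sorted event `data.table` for one participant.
#' @param gap_ms idle-gap threshold in ms.
#' @return list with `events` (the non-marker events plus a `session_idx`
#'   column) and `sessions` (one row per session: `participant_id`,
#'   `session_idx`, `start_ts`, `end_ts`, `n_events`, `dur_session` in
#'   seconds).
#' @export
segment_sessions <- function(events, gap_ms = 8000) {
  is_marker <- events$key_class %in% c("KB_OPEN", "KB_CLOSE")
  keys <- events[!is_marker]
  if (nrow(keys) == 0L) {
    return(list(
      events = keys[, session_idx := integer()],
      sessions = data.table(participant_id = character(),
                            session_idx = integer(), start_ts = numeric(),
                            end_ts = numeric(), n_events = integer(),
                            dur_session = numeric())))
  }
  # marker boundary: any KB_OPEN/KB_CLOSE strictly between two key events
  # forces the later event into a new session
  marker_ts <- events$press_ts[is_marker]
  n <- nrow(keys)
  # running max of releases: rollover typing can release an earlier key
  # after a later one
  prev_release <- cummax(c(-Inf, keys$release_ts))[seq_len(n)]
  gap_break <- keys$press_ts - prev_release > gap_ms
  marker_break <- if (length(marker_ts)) {
    idx_after <- findInterval(marker_ts, keys$press_ts)
    brk <- logical(n)
    hit <- idx_after < n
    brk[idx_after[hit] + 1L] <- TRUE
    brk
  } else {
    logical(n)
  }
  new_session <- gap_break | marker_break
  new_session[1] <- TRUE
  keys[, session_idx := cumsum(new_session)]
  sessions <- keys[, .(start_ts = press_ts[1], end_ts = max(release_ts),
                       n_events = .N), by = .(participant_id, session_idx)]
  sessions[, dur_session := (end_ts - start_ts) / MS_PER_SEC]
  list(events = keys[], sessions = sessions[])
}

#' Flag burst sessions
#'
#' A session is a burst iff it contains `k` consecutive presses whose span
#' is at most `window_ms` — i.e. >= 10 keystrokes occurring within 1 second
#' under the defaults.
#'
#' @param press_ts sorted press timestamps of one session.
#' @param k,window_ms burst parameters.
#' @return logical scalar.
#' @keywords internal
is_burst_session <- function(press_ts, k = 10L, window_ms = 1000) {
  n <- length(press_ts)
  if (n < k) return(FALSE)
  any(press_ts[k:n] - press_ts[1:(n - k + 1L)] <= window_ms)
}

#' Discard burst sessions
#'
#' Removes sessions containing at least one run of `burst_k` consecutive
#' keystrokes within `burst_window_ms`; kept sessions are unchanged.
#'
#' @param segmented result of [segment_sessions()].
#' @param burst_k,burst_window_ms burst parameters (defaults: 10 presses
#'   within 1 s).
#' @return list `events`, `sessions` (kept only), `n_discarded`,
#'   `n_sessions_total`.
#' @export
filter_burst_sessions <- function(segmented, burst_k = 10L,
                                  burst_window_ms = 1000) {
  ev <- segmented$events
  if (nrow(ev) == 0L) {
    return(c(segmented, list(n_discarded = 0L, n_sessions_total = 0L)))
  }
  verdict <- ev[, .(is_burst = is_burst_session(press_ts, burst_k,
                                                burst_window_ms)),
                by = .(participant_id, session_idx)]
  bad <- verdict[is_burst == TRUE]
  list(events = ev[!bad, on = c("participant_id", "session_idx")],
       sessions = segmented$sessions[!bad,
                                     on = c("participant_id", "session_idx")],
       n_discarded = nrow(bad),
       n_sessions_total = nrow(verdict))
}

#' Full preprocessing pipeline for one participant's events
#'
#' Applies, in order: adaptation-week discard, long-hold filter, session
#' segmentation, burst-session exclusion. Every input key event is either
#' in a kept session or attributed to a named filter in `counts`.
#'
#' @param events raw event `data.table` (markers allowed).
#' @param enrollment_date the participant's enrollment date.
#' @param config a [session_config()].
#' @return list `events` (kept, with `session_idx`), `sessions`, and
#'   `counts` (named integer vector: `input_keys`, `adaptation_week`,
#'   `long_hold`, `burst_sessions_events`, `kept`), plus `n_discarded` /
#'   `n_sessions_total` session tallies.
#' @export
preprocess_events <- function(events, enrollment_date,
                              config = session_config()) {
  is_marker <- events$key_class %in% c("KB_OPEN", "KB_CLOSE")
  n_input <- sum(!is_marker)
  e1 <- drop_adaptation_week(events, enrollment_date,
                             config$adaptation_days)
  n1 <- sum(!e1$key_class %in% c("KB_OPEN", "KB_CLOSE"))
  e2 <- filter_long_holds(e1, config$max_hold_ms)
  n2 <- sum(!e2$key_class %in% c("KB_OPEN", "KB_CLOSE"))
  seg <- segment_sessions(e2, config$gap_ms)
  fin <- filter_burst_sessions(seg, config$burst_k, config$burst_window_ms)
  n_kept <- nrow(fin$events)
  counts <- c(input_keys = n_input,
              adaptation_week = n_input - n1,
              long_hold = n1 - n2,
              burst_sessions_events = n2 - n_kept,
              kept = n_kept)
  c(fin, list(counts = counts))
}
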