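# Weekly feature vectors at three temporal resolutions. A weekly vector is
# a T x F array: T = 1 (weekly median), 7 (daily medians, Monday..Sunday)
# or 28 (6-hour medians, 4 periods per day within Monday..Sunday).

RESOLUTIONS <- c(weekly_median = 1L, daily_median = 7L, six_hour_median = 28L)

# window granularity feeding each resolution
.res_window <- c(weekly_median = "week", daily_median = "day",
                 six_hour_median = "six_hour")

#' Slot index of a window inside its week
#'
#' Row order runs Monday to Sunday; within a day, midnight-6 AM, 6 AM-noon,
#' noon-6 PM, 6 PM-midnight. For the 6-hour resolution the slot of
#' (day-of-week d, period p) is `4 * d + p`.
#'
#' @param window_start_ms window start in ms since epoch.
#' @param resolution one of `names(RESOLUTIONS)`.
#' @return integer slot in `0:(T-1)`.
#' @export
week_slot <- function(window_start_ms, resolution) {
  switch(resolution,
         weekly_median = rep(0L, length(window_start_ms)),
         daily_median = as.integer(dow_monday(window_start_ms)),
         six_hour_median = as.integer(4L * dow_monday(window_start_ms) +
                                        six_hour_period_of(window_start_ms)),
         stop("unknown resolution: ", resolution))
}

#' Build weekly feature vectors
#'
#' Arranges per-window feature values into Monday-aligned weekly vectors at
#' the requested temporal resolution. Each cell is the feature's median
#' within its slot (computed upstream by [extract_features()] at the
#' matching granularity). Weeks inside a participant's observed span with
#' no typing data yield all-missing vectors; cells without data are `NA`
#' until [impute_nearest_week()].
#'
#' @param features long feature table from [extract_features()], computed
#'   at `"week"`, `"day"` or `"six_hour"` granularity to match
#'   `resolution`.
#' @param resolution `"weekly_median"`, `"daily_median"` or
#'   `"six_hour_median"`.
#' @param feature_subset optional character vector of features to keep
#'   (default: all 43).
#' @param period_start,period_end optional observation-span bounds (ms);
#'   weeks not fully contained in the span (partial calendar weeks at the
#'   start or end of a record) are dropped.
#' @return long `data.table` `participant_id, week_start, slot, feature,
#'   value` covering the complete (week x slot x feature) grid per
#'   participant, with attributes `resolution`, `T`, `features`.
#' @export
build_weekly_vectors <- function(features,
                                 resolution = c("weekly_median",
                                                "daily_median",
                                                "six_hour_median"),
                                 feature_subset = NULL,
                                 period_start = NULL, period_end = NULL) {
  resolution <- match.arg(resolution)
  want_label <- .res_window[[resolution]]
  if (nrow(features) && !all(features$window_label == want_label)) {
    stop("features must be extracted at '", want_label,
         "' granularity for resolution '", resolution, "'")
  }
  feats <- feature_subset %||% keystroke_features()$feature
  missing_f <- setdiff(feats, unique(features$feature))
  if (nrow(features) && length(missing_f)) {
    stop("features absent from input: ", paste(missing_f, collapse = ", "))
  }
  x <- features[feature %in% feats]
  x <- x[, .(participant_id, week_start = monday_week_start_ms(window_start),
             slot = week_slot(window_start, resolution), feature, value)]
  if (!is.null(period_start)) x <- x[week_start >= period_start]
  if (!is.null(period_end)) x <- x[week_start + MS_PER_WEEK <= period_end]
  T_len <- RESOLUTIONS[[resolution]]
  if (nrow(x) == 0L) {
    out <- data.table(participant_id = character(), week_start = numeric(),
                      slot = integer(), feature = character(),
                      value = numeric())
  } else {
    # complete grid over each participant's span of weeks
    span <- x[, .(week_start = seq(min(week_start), max(week_start),
                                   by = MS_PER_WEEK)),
              by = participant_id]
    grid <- span[, CJ(week_start = week_start, slot = 0:(T_len - 1L),
                      feature = feats, sorted = FALSE),
                 by = participant_id]
    out <- x[grid, on = c("participant_id", "week_start", "slot", "feature")]
    setorder(out, participant_id, week_start, slot, feature)
  }
  setattr(out, "resolution", resolution)
  setattr(out, "T", T_len)
  setattr(out, "features", feats)
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing cells from the nearest week
#'
#' Each missing (slot, feature) cell takes the value of the same cell from
#' the participant's week at minimal absolute week distance, ties broken
#' toward the earlier week. A cell missing in every week of a participant
#' is an error by default; with `on_all_missing = "cohort_median"` it is
#' filled with the cohort-wide median of that (slot, feature) — needed for
#' sparse slots (e.g. small-hours periods of low-activity participants)
#' that a denser real record would cover.
#'
#' @param vectors long table from [build_weekly_vectors()].
#' @param on_all_missing `"error"` or `"cohort_median"`.
#' @return same shape, no missing values; idempotent.
#' @export
impute_nearest_week <- function(vectors,
                                on_all_missing = c("error", "cohort_median")) {
  on_all_missing <- match.arg(on_all_missing)
  out <- copy(vectors)
  if (nrow(out) == 0L || !anyNA(out$value)) return(out)
  setorder(out, participant_id, slot, feature, week_start)
  fill_one <- function(v) {
    obs <- which(!is.na(v))
    if (length(obs) == 0L || length(obs) == length(v)) return(v)
    mis <- which(is.na(v))
    # nearest observed week; which.min returns the first (= earlier) on ties
    nearest <- vapply(mis, function(i) obs[which.min(abs(obs - i))], 0L)
    v[mis] <- v[nearest]
    v
  }
  out[, value := fill_one(value), by = .(participant_id, slot, feature)]
  if (anyNA(out$value)) {
    holes <- unique(out[is.na(value), .(participant_id, slot, feature)])
    if (on_all_missing == "error") {
      h <- holes[1]
      stop(sprintf(paste0("impute_nearest_week: cell (slot %d, %s) of ",
                          "participant %s is missing in every week ",
                          "(%d such cells)"),
                   h$slot, h$feature, h$participant_id, nrow(holes)))
    }
    out[, value := {
      v <- value
      v[is.na(v)] <- median(v, na.rm = TRUE)
      v
    }, by = .(slot, feature)]
    if (anyNA(out$value)) {
      h <- unique(out[is.na(value), .(slot, feature)])[1]
      stop(sprintf(paste0("impute_nearest_week: cell (slot %d, %s) is ",
                          "missing for the entire cohort"),
           h$slot, h$feature))
    }
  }
  for (a in c("resolution", "T", "features")) {
    setattr(out, a, attr(vectors, a))
  }
  out[]
}

#' Flatten weekly vectors into model arrays
#'
#' One sample per (participant, week). Returns both the sequence layout
#' (`x`: n x T x F array, Monday-first row order) and the flat layout
#' (`flat`: n x (T*F) matrix, columns ordered slot-within-feature) used by
#' non-sequential models.
#'
#' @param vectors imputed long table from [impute_nearest_week()].
#' @return list `x`, `flat`, `participant_id`, `week_start`, `features`,
#'   `resolution`.
#' @export
vectors_to_array <- function(vectors) {
  feats <- attr(vectors, "features")
  T_len <- attr(vectors, "T")
  res <- attr(vectors, "resolution")
  v <- copy(vectors)
  v[, fidx := match(feature, feats)]
  setorder(v, participant_id, week_start, fidx, slot)
  keys <- unique(v[, .(participant_id, week_start)])
  n <- nrow(keys)
  # column-major fill: slot fastest, then feature, then sample
  x <- array(v$value, dim = c(T_len, length(feats), n))
  x <- aperm(x, c(3, 1, 2))
  flat <- matrix(x, nrow = n)
  colnames(flat) <- as.vector(outer(0:(T_len - 1L), feats,
                                    function(s, f) paste0(f, "@", s)))
  list(x = x, flat = flat, participant_id = keys$participant_id,
       week_start = keys$week_start, features = feats, resolution = res)
}

#' Min-max normalization over a fit scope
#'
#' Affine map of each (slot, feature) column to `[0, 1]`, fitted on the
#' rows in `fit_rows` (default: the whole dataset, as the study applied it
#' within each constructed dataset; pass the training rows for a
#' leakage-free variant). Values outside the fitted range — possible only
#' off the fit scope — are clipped. Constant columns map to 0.
#'
#' @param flat n x P numeric matrix.
#' @param fit_rows integer row indices defining the fit scope.
#' @return list `x` (normalized matrix) and `scaler` (mins, ranges);
#'   see [apply_scaler()] / [invert_scaler()].
#' @export
minmax_normalize <- function(flat, fit_rows = seq_len(nrow(flat))) {
  sub <- flat[fit_rows, , drop = FALSE]
  mins <- apply(sub, 2, min)
  maxs <- apply(sub, 2, max)
  ranges <- maxs - mins
  scaler <- structure(list(mins = mins, ranges = ranges,
                           cols = colnames(flat)),
                      class = "keydyn_scaler")
  list(x = apply_scaler(scaler, flat), scaler = scaler)
}

#' Apply / invert a fitted min-max scaler
#'
#' @param scaler a `keydyn_scaler` from [minmax_normalize()].
#' @param flat matrix on the original scale (`apply_scaler`) or in `[0, 1]`
#'   (`invert_scaler`).
#' @param clip clip normalized values into `[0, 1]`.
#' @return transformed matrix.
#' @export
apply_scaler <- function(scaler, flat, clip = TRUE) {
  r <- ifelse(scaler$ranges > 0, scaler$ranges, 1)
  out <- sweep(sweep(flat, 2, scaler$mins, "-"), 2, r, "/")
  out[, scaler$ranges == 0] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, flat) {
  r <- ifelse(scaler$ranges > 0, scaler$ranges, 1)
  # constant columns were mapped to 0, so 0 * 1 + min restores them
  sweep(sweep(flat, 2, r, "*"), 2, scaler$mins, "+")
}
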