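# Metrics, ablation harnesses, descriptive age-group curves and
# feature-importance ranking.

#' Mean absolute error and R-squared
#'
#' `MAE = mean |age_hat - age|` over weekly samples;
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about
#' the test-set mean age.
#'
#' @param age true ages (one per weekly sample).
#' @param age_hat estimated ages.
#' @return list with `mae` and `r2`.
#' @export
mae_r2 <- function(age, age_hat) {
  stopifnot(length(age) == length(age_hat), length(age) > 0)
  ss_res <- sum((age - age_hat)^2)
  ss_tot <- sum((age - mean(age))^2)
  list(mae = mean(abs(age_hat - age)),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Mean intraparticipant SD of estimated ages
#'
#' For each participant with at least two weekly predictions, the SD of
#' the estimated ages across weeks; averaged across those participants.
#' This is the week-to-week prediction stability the two-phase loss is
#' designed to improve. Participants with a single week are excluded.
#'
#' @param predictions `data.table`/data.frame with `participant_id` and
#'   `age_hat` (one row per weekly sample).
#' @return non-negative scalar; `NA` if no participant has >= 2 weeks.
#' @export
intraparticipant_sd <- function(predictions) {
  p <- as.data.table(predictions)
  per <- p[, .(n = .N, s = sd(age_hat)), by = participant_id]
  per <- per[n >= 2L]
  if (nrow(per) == 0L) return(NA_real_)
  mean(per$s)
}

#' Average metrics across balanced datasets
#'
#' The final evaluation scores are the arithmetic means of the per-dataset
#' MAE and R-squared values.
#'
#' @param per_dataset `data.table` with columns `dataset_idx, mae, r2`.
#' @return list `mae`, `r2`.
#' @export
average_over_datasets <- function(per_dataset) {
  list(mae = mean(per_dataset$mae), r2 = mean(per_dataset$r2))
}

#' Feature-set ablation
#'
#' Re-runs vectorization and model evaluation restricted to each union of
#' feature categories, recording the feature count and held-out MAE.
#'
#' @param features long feature table from [extract_features()] at the
#'   granularity matching `resolution`.
#' @param cohort manifest with `participant_id`, `age`.
#' @param combos list of character vectors of categories, e.g.
#'   `list(c("speed"), c("speed", "frequency"))`; an empty combo is an
#'   error.
#' @param resolution temporal resolution for the weekly vectors.
#' @param spec_fn function(seed) returning the [model_spec()] to evaluate.
#' @param seed split/fit seed.
#' @param test_frac held-out participant fraction.
#' @param loss optional [loss_config()].
#' @return `data.table` `combo, n_features, mae, r2`.
#' @export
ablate_feature_sets <- function(features, cohort, combos,
                                resolution = "six_hour_median",
                                spec_fn = function(seed)
                                  model_spec("xgboost", seed = seed),
                                seed = 1L, test_frac = 0.3, loss = NULL) {
  rbindlist(lapply(combos, function(combo) {
    if (length(combo) == 0L) stop("empty feature-category combination")
    feats <- keystroke_features(combo)$feature
    vec <- build_weekly_vectors(features, resolution, feature_subset = feats)
    vec <- impute_nearest_week(vec, on_all_missing = "cohort_median")
    data <- assemble_dataset(vec, cohort)
    spec <- spec_fn(seed)
    res <- holdout_eval(data, spec, loss = loss, seed = seed,
                        test_frac = test_frac)
    data.table(combo = paste(combo, collapse = "+"),
               n_features = length(feats), mae = res$mae, r2 = res$r2)
  }))
}

# slots of the 28-step sequence belonging to the given 6-hour periods
.period_slots <- function(periods, T_len = 28L) {
  which((0:(T_len - 1L)) %% 4L %in% periods)
}

#' 6-hour-period ablation
#'
#' Masks the rows of the 28-step (6-hour resolution) weekly sequence to
#' the selected periods of the day — period 0 = midnight-6 AM, 1 =
#' 6 AM-noon, 2 = noon-6 PM, 3 = 6 PM-midnight — keeping rows in
#' chronological order (sequence length `7 * n_periods`), and evaluates a
#' model per mask. The full design evaluates all 15 non-empty masks; the
#' all-period mask reproduces the unablated pipeline exactly given equal
#' seeds.
#'
#' @param data assembled 6-hour dataset from [assemble_dataset()]
#'   (`x` must be n x 28 x F).
#' @param period_masks list of integer vectors (subsets of `0:3`);
#'   `NULL` = all 15 non-empty subsets.
#' @param spec_fn function(seed) returning a sequential [model_spec()].
#' @param seed split/fit seed.
#' @param test_frac held-out participant fraction.
#' @param loss optional [loss_config()].
#' @return `data.table` `mask, n_periods, seq_len, mae, r2`.
#' @export
ablate_periods <- function(data, period_masks = NULL,
                           spec_fn = function(seed)
                             model_spec("lstm", input_layout = "sequence",
                                        seed = seed),
                           seed = 1L, test_frac = 0.3, loss = NULL) {
  stopifnot(dim(data$x)[2] == 28L)
  if (is.null(period_masks)) {
    period_masks <- unlist(lapply(1:4, function(k)
      combn(0:3, k, simplify = FALSE)), recursive = FALSE)
  }
  rbindlist(lapply(period_masks, function(mask) {
    stopifnot(length(mask) >= 1L, all(mask %in% 0:3))
    slots <- .period_slots(sort(unique(mask)))
    sub <- data
    sub$x <- data$x[, slots, , drop = FALSE]
    res <- holdout_eval(sub, spec_fn(seed), loss = loss, seed = seed,
                        test_frac = test_frac)
    data.table(mask = paste(sort(unique(mask)), collapse = ","),
               n_periods = length(unique(mask)),
               seq_len = length(slots), mae = res$mae, r2 = res$r2)
  }))
}

#' Hourly age-group curves (three-step aggregation)
#'
#' For each participant, feature values are collected within every 1-hour
#' window (raw speed values; per-window counts for frequency features);
#' the participant's median is computed per hour of day; the per-hour
#' group value is the mean of these medians across the participants of an
#' age group. Hours with no data for a participant are excluded from that
#' participant's median, and participants with no data at an hour are
#' excluded from the group mean.
#'
#' @param pre preprocessed data from [preprocess_events()].
#' @param cohort manifest with `participant_id`, `age`.
#' @param features features to aggregate (default: the four headline
#'   curves — key presses, sessions, hold time, press-to-press latency).
#' @return `data.table` `feature, age_group, hour, value` (hours 0-23).
#' @export
descriptive_hourly <- function(pre, cohort,
                               features = c("AllKey", "num_session",
                                            "HT", "PPL")) {
  speed_feats <- intersect(features, keystroke_features("speed")$feature)
  freq_feats <- intersect(features,
                          keystroke_features("frequency")$feature)
  bad <- setdiff(features, c(speed_feats, freq_feats))
  if (length(bad)) stop("not base features: ", paste(bad, collapse = ", "))

  parts <- list()
  if (length(speed_feats)) {
    vals <- values_long(pre)[feature %in% speed_feats]
    vals[, hour_of_day := hour_of_day_of(session_start)]
    parts$speed <- vals[, .(med = median(value)),
                        by = .(participant_id, feature, hour_of_day)]
  }
  if (length(freq_feats)) {
    sc <- session_count_table(pre)
    sc[, window_start := floor_window(session_start, "hour")]
    cnt <- sc[, .(AllKey = sum(AllKey), DEL = sum(DEL),
                  num_shift = sum(num_shift), num_session = .N),
              by = .(participant_id, window_start)]
    cnt <- melt(cnt, id.vars = c("participant_id", "window_start"),
                variable.name = "feature", value.name = "value")
    cnt[, feature := as.character(feature)]
    cnt <- cnt[feature %in% freq_feats]
    cnt[, hour_of_day := hour_of_day_of(window_start)]
    parts$freq <- cnt[, .(med = median(as.numeric(value))),
                      by = .(participant_id, feature, hour_of_day)]
  }
  per_part <- rbindlist(parts, use.names = TRUE)
  per_part[as.data.table(cohort), age_group := age_group_of(i.age),
           on = "participant_id"]
  out <- per_part[, .(value = mean(med)),
                  by = .(feature, age_group, hour = hour_of_day)]
  setorder(out, feature, age_group, hour)
  out[]
}

#' Permutation attribution of (feature, period) pairs
#'
#' For a fitted sequential model on 6-hour-median vectors, measures how
#' much each (feature, 6-hour period) pair drives the predictions: the
#' pair's cells (7 day-rows per period) are permuted across samples and
#' the attribution is the mean absolute change in predicted age, averaged
#' over samples. With the 15 speed + frequency features the candidate set
#' has 15 x 4 = 60 pairs. For a flat-layout model the attribution is per
#' feature-column group instead, labeled with `period = NA`.
#'
#' @param model a fitted `keydyn_model`.
#' @param x input array (n x T x F, sequence) or matrix (flat).
#' @param features feature names (length F for sequence layout).
#' @param seed permutation seed.
#' @param n_periods number of within-day periods (4 for 6-hour vectors).
#' @return `data.table` `feature, period, attribution, rank`, sorted by
#'   decreasing attribution.
#' @export
rank_importance <- function(model, x, features, seed = 1L, n_periods = 4L) {
  base <- predict(model, x)
  with_seed(seed, {
    if (model$spec$input_layout == "sequence") {
      T_len <- dim(x)[2]
      stopifnot(length(features) == dim(x)[3])
      grid <- CJ(feature = features, period = 0:(n_periods - 1L),
                 sorted = FALSE)
      att <- mapply(function(f, p) {
        fi <- match(f, features)
        slots <- which((0:(T_len - 1L)) %% n_periods == p)
        perm <- sample(dim(x)[1])
        x2 <- x
        x2[, slots, fi] <- x[perm, slots, fi]
        mean(abs(predict(model, x2) - base))
      }, grid$feature, grid$period)
      out <- data.table(feature = grid$feature, period = grid$period,
                        attribution = att)
    } else {
      stopifnot(!is.null(colnames(x)))
      fgroup <- sub("@[0-9]+$", "", colnames(x))
      out <- rbindlist(lapply(unique(fgroup), function(f) {
        cols <- which(fgroup == f)
        perm <- sample(nrow(x))
        x2 <- x
        x2[, cols] <- x[perm, cols, drop = FALSE]
        data.table(feature = f, period = NA_integer_,
                   attribution = mean(abs(predict(model, x2) - base)))
      }))
    }
  })
  setorder(out, -attribution)
  out[, rank := .I]
  out[]
}
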