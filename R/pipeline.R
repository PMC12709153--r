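# End-to-end helpers: synthetic study simulation, weekly-vector dataset
# assembly, and participant-wise held-out evaluation.

#' Simulate and preprocess a full synthetic study
#'
#' Generates a cohort and one log per participant, runs the preprocessing
#' pipeline (first-week discard, 5-s hold filter, session segmentation,
#' burst exclusion) and pools the kept events and sessions.
#'
#' @param config a [generator_config()].
#' @param session_cfg a [session_config()].
#' @return list `cohort`, `events`, `sessions` (pooled, with
#'   `session_idx` per participant), `n_discarded`, `n_sessions_total`,
#'   `counts` (pooled event-accounting vector).
#' @export
simulate_study <- function(config = generator_config(),
                           session_cfg = session_config()) {
  cohort <- generate_cohort(config)
  pres <- lapply(seq_len(nrow(cohort)), function(i) {
    log <- generate_log(cohort[i], config$n_weeks,
                        seed = config$seed * 10000L + i, config)
    preprocess_events(log, cohort$enrollment_date[i], session_cfg)
  })
  list(cohort = cohort,
       events = rbindlist(lapply(pres, `[[`, "events")),
       sessions = rbindlist(lapply(pres, `[[`, "sessions")),
       n_discarded = sum(vapply(pres, `[[`, 0L, "n_discarded")),
       n_sessions_total = sum(vapply(pres, `[[`, 0L, "n_sessions_total")),
       counts = Reduce(`+`, lapply(pres, `[[`, "counts")))
}

#' Build an imputed weekly-vector dataset from preprocessed events
#'
#' Extracts features at the granularity matching `resolution`, arranges
#' them into Monday-aligned weekly vectors, and imputes missing cells
#' (nearest week, cohort-median fallback for slots empty in every week).
#'
#' @param pre list with `events` and `sessions` (e.g. [simulate_study()]
#'   output or [preprocess_events()]).
#' @param resolution `"weekly_median"`, `"daily_median"` or
#'   `"six_hour_median"`.
#' @param feature_subset features to keep; default the 15 speed +
#'   frequency features (the study's best-performing set).
#' @return imputed long vector table (see [build_weekly_vectors()]).
#' @export
prepare_vectors <- function(pre, resolution = "six_hour_median",
                            feature_subset =
                              keystroke_features(c("speed",
                                                   "frequency"))$feature) {
  gran <- .res_window[[resolution]]
  feats <- extract_features(pre, resolution = gran)
  vec <- build_weekly_vectors(feats, resolution,
                              feature_subset = feature_subset)
  impute_nearest_week(vec, on_all_missing = "cohort_median")
}

#' Assemble model-ready arrays with ages and normalization
#'
#' Flattens the weekly vectors into samples, min-max normalizes each
#' (slot, feature) column over the dataset, and attaches each sample's
#' true age. The sequence array is rebuilt from the normalized columns so
#' flat and sequence layouts see identical values.
#'
#' @param vectors imputed long table from [prepare_vectors()] /
#'   [impute_nearest_week()].
#' @param cohort manifest with `participant_id`, `age`.
#' @param normalize min-max normalize (default TRUE).
#' @return list `x` (n x T x F array), `flat` (n x (T*F) matrix), `age`,
#'   `participant_id`, `week_start`, `features`, `resolution`, `scaler`.
#' @export
assemble_dataset <- function(vectors, cohort, normalize = TRUE) {
  arr <- vectors_to_array(vectors)
  scaler <- NULL
  if (normalize) {
    nm <- minmax_normalize(arr$flat)
    arr$flat <- nm$x
    arr$x <- array(nm$x, dim = dim(arr$x))
    scaler <- nm$scaler
  }
  ages <- as.data.table(cohort)[match(arr$participant_id, participant_id),
                                age]
  c(arr, list(age = ages, scaler = scaler))
}

# participant-wise train/val/test split of an assembled dataset
.split_participants <- function(data, seed, test_frac = 0.25,
                                val_frac = 0.15) {
  ids <- unique(data$participant_id)
  with_seed(seed, {
    shuffled <- sample(ids)
    n <- length(ids)
    n_test <- max(1L, round(test_frac * n))
    n_val <- if (val_frac > 0) max(1L, round(val_frac * n)) else 0L
    list(test = shuffled[seq_len(n_test)],
         val = shuffled[n_test + seq_len(n_val)],
         train = shuffled[-seq_len(n_test + n_val)])
  })
}

.take_rows <- function(data, ids) {
  idx <- which(data$participant_id %in% ids)
  list(x = if (!is.null(data$x)) .subset_x(data$x, idx),
       flat = if (!is.null(data$flat)) data$flat[idx, , drop = FALSE],
       age = data$age[idx],
       participant_id = data$participant_id[idx],
       week_start = data$week_start[idx])
}

#' Participant-wise held-out evaluation of one model
#'
#' Splits participants into train/validation/test sets, fits the model and
#' reports test metrics together with the constant-mean-age baseline
#' (predicting every test sample with the mean training age).
#'
#' @param data assembled dataset from [assemble_dataset()].
#' @param spec a [model_spec()].
#' @param loss optional [loss_config()] for gradient families.
#' @param seed split seed (the spec's own seed drives the fit).
#' @param test_frac,val_frac participant fractions for the held-out test
#'   set and the checkpointing validation set.
#' @return list `mae`, `r2`, `baseline_mae`, `intra_sd`, `predictions`
#'   (`data.table`: `participant_id, week_start, age, age_hat`).
#' @export
holdout_eval <- function(data, spec, loss = NULL, seed = 1L,
                         test_frac = 0.25, val_frac = 0.15) {
  sp <- .split_participants(data, seed, test_frac, val_frac)
  use_flat <- spec$input_layout == "flat"
  pick <- function(d) {
    d$x <- if (use_flat) d$flat else d$x
    d
  }
  train <- pick(.take_rows(data, sp$train))
  val <- if (length(sp$val)) pick(.take_rows(data, sp$val)) else NULL
  test <- pick(.take_rows(data, sp$test))
  model <- fit_age_model(spec, train, val, loss)
  age_hat <- predict(model, test$x)
  m <- mae_r2(test$age, age_hat)
  preds <- data.table(participant_id = test$participant_id,
                      week_start = test$week_start, age = test$age,
                      age_hat = age_hat)
  list(mae = m$mae, r2 = m$r2,
       baseline_mae = mean(abs(test$age - mean(train$age))),
       intra_sd = intraparticipant_sd(preds),
       predictions = preds, model = model)
}

#' Pooled out-of-fold predictions for one balanced dataset
#'
#' Runs participant-wise k-fold cross-validation: for each fold, fits on
#' the other folds and predicts the fold's samples; predictions are pooled
#' and the dataset's MAE/R-squared computed over them.
#'
#' @param data assembled dataset from [assemble_dataset()].
#' @param fold_of named integer vector (participant -> fold), e.g. from
#'   [make_participant_folds()].
#' @param spec a [model_spec()].
#' @param loss optional [loss_config()].
#' @return list `mae`, `r2`, `predictions` (with `fold` column).
#' @export
cv_predict <- function(data, fold_of, spec, loss = NULL) {
  use_flat <- spec$input_layout == "flat"
  pick <- function(d) {
    d$x <- if (use_flat) d$flat else d$x
    d
  }
  folds <- sort(unique(fold_of))
  preds <- rbindlist(lapply(folds, function(f) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- setdiff(names(fold_of), test_ids)
    train <- pick(.take_rows(data, train_ids))
    test <- pick(.take_rows(data, test_ids))
    model <- fit_age_model(spec, train, val = NULL, loss = loss)
    data.table(participant_id = test$participant_id,
               week_start = test$week_start, age = test$age,
               age_hat = predict(model, test$x), fold = f)
  }))
  m <- mae_r2(preds$age, preds$age_hat)
  list(mae = m$mae, r2 = m$r2, predictions = preds)
}
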