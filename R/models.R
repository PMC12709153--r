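# Uniform fit/predict surface over the age-estimation model families.
# Tree and linear families delegate to established implementations
# (ranger, xgboost, glmnet); the gradient families (mlp, lstm, transformer)
# are trained by the package's own loop so the two-phase
# variance-penalized loss applies to them.

GRADIENT_FAMILIES <- c("mlp", "lstm", "transformer")
MODEL_FAMILIES <- c("logistic_regression", "random_forest", "xgboost",
                    GRADIENT_FAMILIES)

#' Specify an age-estimation model
#'
#' Families: `logistic_regression` (L2-regularized multinomial
#' classification over quantile-binned ages whose prediction is the
#' expected age under the class probabilities — the consistent reading of
#' a "logistic regression" applied to a continuous target), `random_forest`,
#' `xgboost`, `mlp`, and the sequential `lstm` and `transformer`.
#' Sequence layout is only valid for the sequential families, and requires
#' vectors with more than one time step (so never the weekly-median
#' resolution).
#'
#' @param family one of `r paste(MODEL_FAMILIES, collapse = ", ")`.
#' @param hyperparameters named list; unset entries use small fast
#'   defaults per family (`hidden`, `lr`, `batch_size`, `epochs`,
#'   `num_trees`, `max_depth`, `nrounds`, `eta`, `lambda`, ...).
#' @param input_layout `"flat"` (n x P matrix) or `"sequence"`
#'   (n x T x F array).
#' @param seed integer seed controlling every stochastic component of the
#'   fit.
#' @return a `keydyn_model_spec`.
#' @export
model_spec <- function(family, hyperparameters = list(),
                       input_layout = c("flat", "sequence"), seed = 1L) {
  if (family %in% c("catboost", "tabnet")) {
    stop("model family '", family, "' is not provided by this package; ",
         "available families: ", paste(MODEL_FAMILIES, collapse = ", "))
  }
  family <- match.arg(family, MODEL_FAMILIES)
  input_layout <- match.arg(input_layout)
  if (input_layout == "sequence" && !family %in% c("lstm", "transformer")) {
    stop("sequence layout is only valid for lstm/transformer models")
  }
  if (family %in% c("lstm", "transformer") && input_layout != "sequence") {
    stop("family '", family, "' requires the sequence input layout")
  }
  structure(list(family = family, hyperparameters = hyperparameters,
                 input_layout = input_layout, seed = as.integer(seed)),
            class = "keydyn_model_spec")
}

.check_layout <- function(spec, x) {
  nd <- length(dim(x))
  if (spec$input_layout == "sequence") {
    if (nd != 3L) stop("sequence models need an n x T x F array")
    if (dim(x)[2] < 2L) {
      stop("sequence layout needs more than one time step per week; ",
           "weekly-median vectors (T = 1) cannot feed a sequential model")
    }
  } else if (nd != 2L) {
    stop("flat models need an n x P matrix")
  }
}

#' Fit an age-estimation model
#'
#' Dispatches on the spec's family. Gradient families run the two-phase
#' loop of [two_phase_train()] (plain L1 when `loss` is `NULL`); tree and
#' linear families fit deterministically given the seed.
#'
#' @param spec a [model_spec()].
#' @param train list with `x` (layout matching the spec), `age`, and
#'   `participant_id`.
#' @param val optional validation list of the same shape (used by the
#'   gradient families for best-epoch checkpointing).
#' @param loss optional [loss_config()] enabling the variance-penalized
#'   two-phase training (gradient families only).
#' @return a fitted `keydyn_model`; use [predict()] with new `x`.
#' @export
fit_age_model <- function(spec, train, val = NULL, loss = NULL) {
  stopifnot(inherits(spec, "keydyn_model_spec"))
  .check_layout(spec, train$x)
  if (length(train$age) == 0L) stop("empty training set")
  hy <- spec$hyperparameters

  if (spec$family %in% GRADIENT_FAMILIES) {
    if (is.null(loss)) {
      # conventional training = degenerate two-phase loop (phase 2 only)
      loss <- loss_config(threshold = 1, weight = 0, phase1_epochs = 0L,
                          phase2_epochs = hy$epochs %||% 30L)
    }
    return(two_phase_train(spec, train, val, loss))
  }

  fit <- switch(
    spec$family,
    logistic_regression = {
      # multinomial classes are quantile bins of the training ages (every
      # class needs enough members); each class is valued at its mean age
      # and the prediction is the probability-weighted expected age
      n_bins <- hy$n_bins %||% max(2L, min(12L, length(train$age) %/% 8L))
      breaks <- unique(stats::quantile(train$age,
                                       probs = seq(0, 1,
                                                   length.out = n_bins + 1)))
      cls <- cut(train$age, breaks, include.lowest = TRUE)
      class_age <- tapply(train$age, cls, mean)
      gfit <- with_seed(spec$seed, glmnet::glmnet(
        train$x, cls, family = "multinomial", alpha = 0,
        lambda = hy$lambda %||% 0.05))
      list(glmnet = gfit, ages = as.numeric(class_age),
           lambda = hy$lambda %||% 0.05)
    },
    random_forest = {
      ranger::ranger(
        x = train$x, y = train$age,
        num.trees = hy$num_trees %||% 300L,
        max.depth = hy$max_depth %||% 0L,
        mtry = hy$mtry %||% NULL,
        seed = spec$seed, num.threads = 1L)
    },
    xgboost = {
      xgboost::xgboost(
        x = train$x, y = train$age,
        objective = "reg:squarederror",
        nrounds = hy$nrounds %||% 150L,
        max_depth = hy$max_depth %||% 4L,
        learning_rate = hy$learning_rate %||% 0.1,
        nthreads = 1L, verbosity = 0L,
        seed = spec$seed)
    })
  structure(list(spec = spec, family = spec$family, fit = fit),
            class = "keydyn_model")
}

#' Predict ages from a fitted model
#'
#' @param object a `keydyn_model`.
#' @param newdata `x` in the layout the model was fitted with.
#' @param ... unused.
#' @return numeric vector of estimated ages.
#' @export
predict.keydyn_model <- function(object, newdata, ...) {
  .check_layout(object$spec, newdata)
  switch(
    object$family,
    mlp = ,
    lstm = ,
    transformer = nn_predict(object$net, newdata) + object$y_center,
    logistic_regression = {
      pr <- predict(object$fit$glmnet, newdata, type = "response",
                    s = object$fit$lambda)[, , 1]
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
      drop(pr %*% object$fit$ages)
    },
    random_forest = predict(object$fit, data = newdata,
                            num.threads = 1L)$predictions,
    xgboost = predict(object$fit, newdata))
}

#' @export
print.keydyn_model <- function(x, ...) {
  cat("<keydyn_model>", x$family, "(", x$spec$input_layout, "layout )\n")
  if (!is.null(x$val_mae)) {
    cat("  best checkpoint MAE:", round(x$val_mae, 3), "years\n")
  }
  invisible(x)
}
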