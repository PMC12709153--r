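# shared small synthetic regression problems
flat_problem <- function(n = 60, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  age <- 20 + 30 * x[, 1] + rnorm(n, 0, 2)
  list(x = x, age = age, participant_id = sprintf("P%02d", seq_len(n)))
}

seq_problem <- function(n = 50, T_len = 6, F_len = 3, seed = 2,
                        weeks_per_participant = 1) {
  set.seed(seed)
  x <- array(runif(n * T_len * F_len), c(n, T_len, F_len))
  age <- 20 + 30 * apply(x[, , 1, drop = FALSE], 1, mean) + rnorm(n, 0, 1)
  pid <- sprintf("P%02d", ceiling(seq_len(n) / weeks_per_participant))
  list(x = x, age = age, participant_id = pid)
}

test_that("model specs enforce layout and family constraints", {
  expect_error(model_spec("lstm", input_layout = "flat"), "sequence")
  expect_error(model_spec("random_forest", input_layout = "sequence"),
               "only valid for lstm/transformer")
  expect_error(model_spec("catboost"), "not provided")
  expect_error(model_spec("tabnet"), "not provided")
  spec <- model_spec("lstm", input_layout = "sequence")
  # weekly-median vectors (T = 1) cannot feed a sequential model
  weekly <- list(x = array(runif(10), c(10, 1, 1)), age = rep(30, 10),
                 participant_id = sprintf("P%d", 1:10))
  expect_error(fit_age_model(spec, weekly), "more than one time step")
  flat <- flat_problem(10)
  expect_error(fit_age_model(model_spec("random_forest"),
                             list(x = flat$x[0, ], age = numeric(0),
                                  participant_id = character(0))),
               "empty training set")
})

test_that("tree and linear families beat the constant-age baseline", {
  prob <- flat_problem(80)
  baseline <- mean(abs(prob$age - mean(prob$age)))
  for (family in c("random_forest", "xgboost", "logistic_regression")) {
    model <- fit_age_model(model_spec(family, seed = 3), prob)
    mae <- mean(abs(predict(model, prob$x) - prob$age))
    expect_lt(mae, baseline)
  }
})

test_that("seeded fits are deterministic", {
  prob <- flat_problem(40)
  for (family in c("random_forest", "xgboost")) {
    m1 <- fit_age_model(model_spec(family, seed = 7), prob)
    m2 <- fit_age_model(model_spec(family, seed = 7), prob)
    expect_identical(predict(m1, prob$x), predict(m2, prob$x))
  }
  sp <- seq_problem(20)
  spec <- model_spec("lstm", list(hidden = 4L, epochs = 3L),
                     "sequence", seed = 9)
  m1 <- fit_age_model(spec, sp)
  m2 <- fit_age_model(spec, sp)
  expect_identical(predict(m1, sp$x), predict(m2, sp$x))
})

test_that("expected-age classification predicts inside the training range", {
  prob <- flat_problem(50, seed = 4)
  model <- fit_age_model(model_spec("logistic_regression", seed = 1), prob)
  preds <- predict(model, matrix(runif(40 * 5, -2, 3), 40, 5))
  expect_true(all(preds >= min(round(prob$age))))
  expect_true(all(preds <= max(round(prob$age))))
})

test_that("penalized batch loss follows the two-phase rule", {
  cfg <- loss_config(threshold = 2, weight = 0.4)
  # batch with mean L1 error m = 2.5 > threshold: loss = m + 0.4 m = 3.5
  expect_equal(penalized_batch_loss(c(32, 33), c(30, 30), cfg, phase = 1),
               3.5)
  # m = 1.5 below threshold: no penalty
  expect_equal(penalized_batch_loss(c(31, 32), c(30, 30), cfg, phase = 1),
               1.5)
  # phase 2 is plain L1 regardless of m
  expect_equal(penalized_batch_loss(c(32, 33), c(30, 30), cfg, phase = 2),
               2.5)
  expect_error(penalized_batch_loss(numeric(0), numeric(0), cfg), "empty")

  # weight 0 equals plain L1 everywhere; monotone non-decreasing in m
  cfg0 <- loss_config(threshold = 2, weight = 0)
  ms <- seq(0, 6, by = 0.25)
  l0 <- vapply(ms, function(m)
    penalized_batch_loss(30 + m, 30, cfg0, 1), 0)
  expect_equal(l0, ms)
  l1 <- vapply(ms, function(m)
    penalized_batch_loss(30 + m, 30, cfg, 1), 0)
  expect_true(all(diff(l1) >= 0))
  expect_equal(l1[ms <= 2], ms[ms <= 2])
  expect_equal(l1[ms > 2], 1.4 * ms[ms > 2])
})

test_that("participant batches never mix participants and cover all weeks", {
  pid <- rep(c("A", "B", "C"), c(5, 12, 3))
  b <- participant_batches(pid, batch_size = 8L, seed = 1)
  for (idx in b) expect_equal(length(unique(pid[idx])), 1L)
  expect_setequal(unlist(b), seq_along(pid))
  expect_true(all(lengths(b) <= 8))
  # participant with 5 weeks and batch size 8 -> a single batch of 5
  expect_equal(sort(lengths(b)[vapply(b, function(i) pid[i[1]] == "A",
                                      TRUE)]), 5L)
  b2 <- participant_batches(pid, batch_size = 8L, seed = 2)
  expect_false(identical(b, b2))
})

numeric_grad <- function(net, x, y, cfg, k, eps = 1e-5) {
  p <- net$params[[k]]
  g <- p * 0
  for (i in seq_along(p)) {
    lp <- lm <- net
    lp$params[[k]][i] <- p[i] + eps
    lm$params[[k]][i] <- p[i] - eps
    fp <- keydyn:::nn_forward(lp, x, train = FALSE)$pred
    fm <- keydyn:::nn_forward(lm, x, train = FALSE)$pred
    g[i] <- (penalized_batch_loss(fp, y, cfg, 1L) -
               penalized_batch_loss(fm, y, cfg, 1L)) / (2 * eps)
  }
  g
}

test_that("analytic gradients match numerical differentiation", {
  cfg <- loss_config(threshold = 0.5, weight = 0.4)
  set.seed(11)
  cases <- list(
    list(family = "mlp", hy = list(hidden = c(5L, 4L), dropout = 0),
         x = matrix(rnorm(6 * 8), 6, 8)),
    list(family = "lstm", hy = list(hidden = 5L),
         x = array(rnorm(4 * 5 * 3), c(4, 5, 3))),
    list(family = "transformer", hy = list(d_model = 6L, d_ff = 7L),
         x = array(rnorm(3 * 5 * 4), c(3, 5, 4))))
  for (case in cases) {
    y <- rnorm(dim(case$x)[1], 2)
    dims <- dim(case$x)
    net <- keydyn:::nn_init(case$family, dims[length(dims)],
                            if (length(dims) == 3) dims[2] else NULL,
                            case$hy, seed = 42)
    fw <- keydyn:::nn_forward(net, case$x, train = FALSE)
    dpred <- keydyn:::.loss_grad(fw$pred, y, cfg, 1L)
    analytic <- keydyn:::nn_backward(net, fw, dpred)
    for (k in names(net$params)) {
      ng <- numeric_grad(net, case$x, y, cfg, k)
      expect_lt(max(abs(analytic[[k]] - ng)) / (max(abs(ng)) + 1e-8),
                1e-6)
    }
  }
})

test_that("gradient families learn a planted linear signal", {
  prob <- flat_problem(80, seed = 5)
  baseline <- mean(abs(prob$age - mean(prob$age)))
  mlp <- fit_age_model(model_spec("mlp", list(hidden = c(16L, 8L),
                                              epochs = 60L, lr = 0.02),
                                  seed = 1), prob)
  expect_lt(mean(abs(predict(mlp, prob$x) - prob$age)), baseline)

  sp <- seq_problem(60, seed = 6)
  base_seq <- mean(abs(sp$age - mean(sp$age)))
  for (family in c("lstm", "transformer")) {
    spec <- model_spec(family, list(hidden = 8L, d_model = 8L, lr = 0.05,
                                    epochs = 50L), "sequence", seed = 2)
    m <- fit_age_model(spec, sp)
    expect_lt(mean(abs(predict(m, sp$x) - sp$age)), base_seq)
  }
})

test_that("zero phase-1 epochs reproduce conventional training exactly", {
  sp <- seq_problem(30, seed = 8, weeks_per_participant = 3)
  spec <- model_spec("lstm", list(hidden = 4L, epochs = 10L), "sequence",
                     seed = 5)
  plain <- fit_age_model(spec, sp)
  degenerate <- two_phase_train(spec, sp,
                                config = loss_config(threshold = 3,
                                                     weight = 0.8,
                                                     phase1_epochs = 0L,
                                                     phase2_epochs = 10L))
  expect_identical(predict(plain, sp$x), predict(degenerate, sp$x))
})

test_that("two-phase training returns the best-validation checkpoint", {
  sp <- seq_problem(40, seed = 9, weeks_per_participant = 4)
  val <- seq_problem(12, seed = 10, weeks_per_participant = 3)
  spec <- model_spec("lstm", list(hidden = 6L, lr = 0.05), "sequence",
                     seed = 3)
  m <- two_phase_train(spec, sp, val,
                       loss_config(2, 0.4, phase1_epochs = 8L,
                                   phase2_epochs = 8L))
  expect_s3_class(m, "keydyn_model")
  val_mae <- mean(abs(predict(m, val$x) - val$age))
  expect_equal(val_mae, m$val_mae, tolerance = 1e-9)
})
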