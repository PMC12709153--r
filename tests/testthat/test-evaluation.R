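test_that("MAE and R-squared follow their definitions", {
  perfect <- mae_r2(c(20, 30, 40), c(20, 30, 40))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)

  const <- mae_r2(c(20, 30, 40), rep(30, 3))  # test-mean predictor
  expect_equal(const$r2, 0)

  m <- mae_r2(c(20, 30, 40), c(22, 29, 44))
  expect_equal(m$mae, (2 + 1 + 4) / 3)
  expect_equal(m$r2, 1 - 21 / 200)

  set.seed(2)
  for (i in 1:30) {
    y <- rnorm(sample(3:50, 1), 35, 8)
    yhat <- y + rnorm(length(y), 0, 3)
    o <- oracle_mae_r2(y, yhat)
    got <- mae_r2(y, yhat)
    expect_equal(got$mae, o$mae, tolerance = 1e-12)
    expect_equal(got$r2, o$r2, tolerance = 1e-12)
  }
})

test_that("intraparticipant SD averages per-participant weekly spread", {
  pred <- data.table::data.table(
    participant_id = rep(c("A", "B"), each = 3),
    age_hat = c(1, 2, 3, 2, 4, 6))  # SDs 1 and 2
  expect_equal(intraparticipant_sd(pred), 1.5)

  constant <- data.table::data.table(participant_id = rep("A", 5),
                                     age_hat = rep(31.2, 5))
  expect_equal(intraparticipant_sd(constant), 0)

  # singletons are excluded
  with_single <- rbind(pred, data.table::data.table(participant_id = "C",
                                                    age_hat = 99))
  expect_equal(intraparticipant_sd(with_single), 1.5)

  set.seed(4)
  for (i in 1:30) {
    tab <- data.table::data.table(
      participant_id = sample(LETTERS[1:6], 40, TRUE),
      age_hat = rnorm(40, 35, 5))
    expect_equal(intraparticipant_sd(tab), oracle_intra_sd(tab),
                 tolerance = 1e-12)
  }
})

test_that("final scores are arithmetic means over the 7 datasets", {
  per <- data.table::data.table(dataset_idx = 1:7,
                                mae = c(3.5, 3.7, 3.6, 3.9, 3.4, 3.8, 3.6),
                                r2 = seq(0.60, 0.72, by = 0.02))
  avg <- average_over_datasets(per)
  expect_equal(avg$mae, sum(per$mae) / 7)
  expect_equal(avg$r2, sum(per$r2) / 7)
})

test_that("feature-set ablation selects the catalog unions", {
  st <- tiny_study()
  feats <- extract_features(st, resolution = "week")
  tab <- ablate_feature_sets(
    feats, st$cohort,
    combos = list("speed", c("speed", "frequency")),
    resolution = "weekly_median", seed = 2)
  expect_equal(tab$n_features, c(11L, 15L))
  expect_equal(tab$combo, c("speed", "speed+frequency"))
  expect_true(all(is.finite(tab$mae)))
  expect_error(ablate_feature_sets(feats, st$cohort,
                                   combos = list(character(0)),
                                   resolution = "weekly_median"),
               "empty")
})

test_that("period ablation masks the 28-step sequence chronologically", {
  st <- tiny_study()
  v <- prepare_vectors(st, "six_hour_median")
  d <- assemble_dataset(v, st$cohort)
  spec_fn <- function(seed) model_spec("lstm",
                                       list(hidden = 4L, epochs = 4L),
                                       "sequence", seed = seed)
  full <- ablate_periods(d, period_masks = NULL, spec_fn = spec_fn,
                         seed = 3, test_frac = 0.3)
  expect_equal(nrow(full), 15L)  # 2^4 - 1 non-empty masks
  expect_equal(full$seq_len, 7L * full$n_periods)
  expect_equal(full[n_periods == 4, seq_len], 28L)

  # the all-period mask reproduces the unablated pipeline bit for bit
  direct <- holdout_eval(d, spec_fn(3), seed = 3, test_frac = 0.3)
  expect_identical(full[mask == "0,1,2,3", mae], direct$mae)
})

test_that("hourly curves implement the three-step aggregation", {
  hour <- 3600e3
  day10 <- 10 * 86400e3
  # P1 types with 2-s press-to-press latency, P2 with 4-s, same hour
  p1 <- make_events(day10 + 10 * hour + c(0, 2000, 4000),
                    participant_id = "P1")
  p2 <- make_events(day10 + 10 * hour + c(0, 4000, 8000),
                    participant_id = "P2")
  pre <- as_pre(rbind(p1, p2))
  cohort <- data.table::data.table(participant_id = c("P1", "P2"),
                                   age = c(25, 27))
  curves <- descriptive_hourly(pre, cohort, features = "PPL")
  expect_equal(curves[hour == 10, value], 3)  # mean of medians 2 and 4
  expect_equal(nrow(curves), 1L)  # hours without data are absent

  # permutation invariance in participant order
  pre_rev <- as_pre(rbind(p2, p1))
  curves_rev <- descriptive_hourly(pre_rev, cohort, features = "PPL")
  expect_equal(curves_rev$value, curves$value)

  # constant feature gives a flat curve at the constant
  p3 <- make_events(day10 + c(8, 12, 15) * hour + c(0, 0, 0),
                    release = day10 + c(8, 12, 15) * hour + 100,
                    participant_id = "P3")
  flat <- descriptive_hourly(as_pre(p3),
                             data.table::data.table(participant_id = "P3",
                                                    age = 40),
                             features = "HT")
  expect_equal(flat$value, rep(0.1, 3))
})

test_that("permutation attribution recovers a planted sequential signal", {
  feats <- keystroke_features(c("speed", "frequency"))$feature
  n <- 80
  set.seed(12)
  x <- array(runif(n * 28 * 15), c(n, 28, 15))
  ht <- match("HT", feats)
  ppl <- match("PPL", feats)
  x[, , ht] <- 0.5  # constant across the dataset
  age <- 20 + 30 * apply(x[, , ppl], 1, mean) + rnorm(n, 0, 0.5)
  prob <- list(x = x, age = age, participant_id = sprintf("P%02d", 1:n))
  spec <- model_spec("lstm", list(hidden = 8L, lr = 0.05, epochs = 40L),
                     "sequence", seed = 4)
  model <- fit_age_model(spec, prob)

  imp <- rank_importance(model, x, feats, seed = 1)
  expect_equal(nrow(imp), 60L)  # 15 features x 4 periods
  expect_equal(imp[feature == "HT", attribution], rep(0, 4))
  # the planted feature tops the ranking (the LSTM weights late
  # timesteps most, so its strongest period carries the signal)
  expect_equal(imp[rank == 1, feature], "PPL")
})
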