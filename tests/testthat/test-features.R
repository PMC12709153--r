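test_that("the feature inventory matches the 43-feature catalog", {
  cat <- keystroke_features()
  expect_equal(nrow(cat), 43L)
  expect_equal(as.vector(table(factor(cat$category,
                                      c("speed", "frequency",
                                        "speed_variability",
                                        "frequency_variability")))),
               c(11L, 4L, 22L, 6L))
  expect_false(anyDuplicated(cat$feature) > 0)
  # num_session has no variability companion
  expect_false(any(grepl("num_session_", cat$feature)))
  expect_equal(nrow(keystroke_features(c("speed", "frequency"))), 15L)
  expect_error(keystroke_features("velocity"), "unknown")
})

test_that("per-event speed series follow their definitions", {
  s <- make_events(c(100, 250), release = c(180, 400))
  ser <- event_speed_series(s)
  expect_equal(ser$HT, c(0.08, 0.15))
  expect_equal(ser$FT, 0.07)
  expect_equal(ser$PPL, 0.15)
  expect_equal(ser$RRL, 0.22)

  s2 <- make_events(c(0, 150, 300), release = c(80, 260, 380),
                    key_class = c("char", "delete", "char"))
  ser2 <- event_speed_series(s2)
  expect_equal(ser2$precorrection, 0.07)
  expect_equal(ser2$correction, 0.11)
  expect_equal(ser2$postcorrection, 0.04)

  # rollover: second press before first release gives a negative FT
  s3 <- make_events(c(0, 150), release = c(180, 300))
  expect_equal(event_speed_series(s3)$FT, -0.03)

  # single-event session: pairwise series are empty
  ser1 <- event_speed_series(make_events(0, release = 90))
  expect_equal(ser1$HT, 0.09)
  expect_length(ser1$FT, 0)
  expect_length(ser1$PPL, 0)
})

test_that("session scalars: rates, shift duration, degenerate sessions", {
  press <- seq(0, by = 10000 / 29, length.out = 30)
  cls <- rep("char", 30)
  cls[c(3, 10, 20)] <- "delete"
  s <- make_events(press, release = c(press[-30] + 50, press[30] + 10000 -
                                        press[30]), key_class = cls)
  # force dur_session = 10 s exactly
  s$release_ts[30] <- 10000
  sc <- session_scalars(s)
  expect_equal(sc$AllKeyRate, 3.0)
  expect_equal(sc$DELRate, 0.3)
  expect_equal(sc$dur_session, 10)

  expect_length(event_speed_series(s)$dur_shift, 0)

  sh <- make_events(c(1000, 1400), key_class = c("layout_shift", "char"))
  expect_equal(event_speed_series(sh)$dur_shift, 0.4)

  # instantaneous single event: rates undefined
  inst <- make_events(100, release = 100)
  expect_true(is.na(session_scalars(inst)$AllKeyRate))
})

test_that("window frequency counts sessions by their start timestamp", {
  hour <- 3600e3
  s1 <- make_events(seq(0, by = 200, length.out = 5))
  s2 <- make_events(seq(20000, by = 200, length.out = 7))
  # session straddling the hour boundary, starting inside hour 0
  s3 <- make_events(seq(hour - 400, by = 200, length.out = 4),
                    key_class = c("char", "delete", "char", "char"))
  pre <- as_pre(rbind(s1, s2, s3))
  w <- window_frequency(pre, 0, hour)
  expect_equal(w$AllKey, 16L)
  expect_equal(w$num_session, 3L)
  expect_equal(w$DEL, 1L)
  w2 <- window_frequency(pre, hour, 2 * hour)
  expect_equal(w2$num_session, 0L)
  expect_equal(w2$AllKey, 0L)
})

test_that("max_gap matches the interpolated-percentile oracle", {
  expect_equal(max_gap(rep(5, 4)), 0)
  expect_equal(max_gap(3), 0)
  expect_equal(max_gap(1:100), 89.10, tolerance = 1e-12)
  expect_equal(oracle_max_gap(1:100), 89.10, tolerance = 1e-12)
  expect_true(is.na(max_gap(numeric(0))))
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(sample(2:80, 1))
    expect_equal(max_gap(x), oracle_max_gap(x), tolerance = 1e-9)
    expect_gte(max_gap(x), 0)
    expect_equal(pop_sd(x), oracle_pop_sd(x), tolerance = 1e-9)
  }
})

test_that("extract_features emits exactly the 43-name inventory", {
  day <- 86400e3
  hour <- 3600e3
  # three sessions in three hours of one day with 10/20/30 char presses
  mk <- function(h, n) make_events(seq(h * hour, by = 300, length.out = n))
  pre <- as_pre(rbind(mk(9, 10), mk(10, 20), mk(11, 30)))
  f <- extract_features(pre, resolution = "day")
  expect_equal(sort(unique(f$feature)), sort(keystroke_features()$feature))
  expect_equal(nrow(f), 43L)

  g <- function(name) f[feature == name, value]
  expect_equal(g("AllKey"), 60)
  expect_equal(g("num_session"), 3)
  expect_equal(g("AllKey_STD"), oracle_pop_sd(c(10, 20, 30)))
  expect_equal(g("AllKey_STD"), 8.1649658, tolerance = 1e-6)
  expect_equal(g("AllKey_MaxGap"), oracle_max_gap(c(10, 20, 30)))
  expect_equal(g("DEL"), 0)
  expect_true(is.na(g("dur_shift")))  # no layout shifts in this log

  # constant hold time: HT median exact, variability 0
  const <- make_events(seq(0, by = 500, length.out = 10),
                       release = seq(0, by = 500, length.out = 10) + 100)
  fc <- extract_features(as_pre(const), resolution = "week")
  expect_equal(fc[feature == "HT", value], 0.1)
  expect_equal(fc[feature == "HT_STD", value], 0)
  expect_equal(fc[feature == "HT_MaxGap", value], 0)
})

test_that("speed medians scale with latency and rates scale inversely", {
  press <- cumsum(c(0, runif(29, 100, 400)))
  ev <- make_events(press, release = press + runif(30, 40, 200))
  doubled <- data.table::copy(ev)
  doubled[, `:=`(press_ts = 2 * press_ts, release_ts = 2 * release_ts)]
  f1 <- extract_features(as_pre(ev), resolution = "week")
  f2 <- extract_features(as_pre(doubled), resolution = "week")
  for (feat in c("HT", "FT", "PPL", "RRL")) {
    expect_equal(f2[feature == feat, value],
                 2 * f1[feature == feat, value], tolerance = 1e-9)
  }
  expect_equal(f2[feature == "AllKeyRate", value],
               f1[feature == "AllKeyRate", value] / 2, tolerance = 1e-9)
})

test_that("windowed medians agree with direct recomputation on a study", {
  st <- tiny_study()
  f <- extract_features(st, resolution = "six_hour")
  expect_equal(unique(f[, .N, by = .(participant_id, window_start)]$N), 43L)
  # spot-check one window's PPL median against a brute-force filter
  w <- f[feature == "PPL" & !is.na(value)][3]
  sess <- st$sessions[participant_id == w$participant_id &
                        start_ts >= w$window_start &
                        start_ts < w$window_start + 6 * 3600e3]
  ev <- st$events[sess, on = c("participant_id", "session_idx")]
  ppl <- ev[, diff(press_ts), by = session_idx]$V1 / 1000
  expect_equal(w$value, median(ppl))
})
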