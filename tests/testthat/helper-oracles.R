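# Independent brute-force oracles: deliberately naive implementations used
# only to verify the package's vectorized paths.

# linear-interpolation percentile at position 1 + q * (n - 1)
oracle_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + q * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_max_gap <- function(x) {
  oracle_quantile(x, 0.95) - oracle_quantile(x, 0.05)
}

oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

# gap-rule session ids by explicit scan (no markers)
oracle_segment <- function(press, release, gap_ms = 8000) {
  n <- length(press)
  id <- integer(n)
  cur <- 1L
  id[1] <- 1L
  for (i in seq_len(n)[-1]) {
    if (press[i] - max(release[seq_len(i - 1)]) > gap_ms) cur <- cur + 1L
    id[i] <- cur
  }
  id
}

# burst verdict by checking every k-window explicitly
oracle_burst <- function(press, k = 10L, window_ms = 1000) {
  n <- length(press)
  if (n < k) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    if (press[i + k - 1L] - press[i] <= window_ms) return(TRUE)
  }
  FALSE
}

oracle_mae_r2 <- function(y, yhat) {
  list(mae = sum(abs(y - yhat)) / length(y),
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}

oracle_intra_sd <- function(pred) {
  ids <- unique(pred$participant_id)
  sds <- c()
  for (p in ids) {
    v <- pred$age_hat[pred$participant_id == p]
    if (length(v) >= 2) sds <- c(sds, stats::sd(v))
  }
  mean(sds)
}

# random small event log: clustered presses with occasional long gaps
random_log <- function(n, seed) {
  set.seed(seed)
  gaps <- ifelse(runif(n) < 0.12, runif(n, 8001, 40000),
                 runif(n, 30, 4000))
  press <- cumsum(gaps)
  hold <- runif(n, 20, 600)
  data.table::data.table(press_ts = press, release_ts = press + hold,
                         key_class = sample(c("char", "delete",
                                              "layout_shift"),
                                            n, TRUE, c(0.8, 0.12, 0.08)),
                         participant_id = "P1")
}
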