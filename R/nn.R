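# Gradient-trained age estimators (MLP, LSTM, single-head transformer
# encoder) written directly in R: forward/backward passes with Adam,
# plateau learning-rate decay, best-validation checkpointing, and the
# two-phase training loop whose first phase penalizes intraparticipant
# spread of the predicted age through participant-grouped mini-batches.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Configuration of the variance-penalized two-phase loss
#'
#' Phase 1 trains on participant-grouped mini-batches: the batch loss is
#' the mean L1 error `m` of that participant's weekly samples, and when `m`
#' exceeds `threshold` (years) a penalty `weight * m` is added — pushing
#' the model to keep a participant's week-to-week predictions tight. Phase
#' 2 continues with conventional mixed batches and the plain L1 loss.
#'
#' @param threshold penalty threshold in years (study grid: 1, 2, 3).
#' @param weight penalty weight in `[0, 1]` (study grid: 0.2-1.0; 0 gives
#'   plain L1 training).
#' @param phase1_epochs,phase2_epochs epochs per phase.
#' @return a `keydyn_loss_config` list.
#' @export
loss_config <- function(threshold = 2, weight = 0.4, phase1_epochs = 10L,
                        phase2_epochs = 20L) {
  stopifnot(threshold > 0, weight >= 0, weight <= 1,
            phase1_epochs >= 0, phase2_epochs >= 0)
  structure(list(threshold = threshold, weight = weight,
                 phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs)),
            class = "keydyn_loss_config")
}

#' Batch loss with the intraparticipant-variance penalty
#'
#' Let `m` be the mean absolute error over the batch. In phase 1 the loss
#' is `m + weight * m` when `m > threshold` and `m` otherwise; in phase 2
#' it is the plain `m`. Phase-1 batches must contain a single participant's
#' samples for the penalty to act on intraparticipant deviation.
#'
#' @param predictions,true_age numeric vectors of equal positive length.
#' @param config a [loss_config()].
#' @param phase 1 or 2.
#' @return scalar loss.
#' @export
penalized_batch_loss <- function(predictions, true_age, config, phase = 1L) {
  if (length(predictions) == 0L) stop("empty batch")
  stopifnot(length(predictions) == length(true_age), phase %in% c(1L, 2L))
  m <- mean(abs(predictions - true_age))
  if (phase == 1L && m > config$threshold) m * (1 + config$weight) else m
}

# gradient of the batch loss w.r.t. predictions
.loss_grad <- function(predictions, true_age, config, phase) {
  n <- length(predictions)
  m <- mean(abs(predictions - true_age))
  scale <- if (phase == 1L && m > config$threshold) 1 + config$weight else 1
  scale * sign(predictions - true_age) / n
}

#' Participant-grouped mini-batches
#'
#' Splits sample indices so that every batch contains samples of exactly
#' one participant (at most `batch_size` of them), covers every sample, and
#' is returned in an order shuffled by `seed`.
#'
#' @param participant_id character vector, one entry per sample.
#' @param batch_size maximal batch size.
#' @param seed integer seed for the shuffle.
#' @return list of integer index vectors.
#' @export
participant_batches <- function(participant_id, batch_size = 32L, seed = 1L) {
  with_seed(seed, {
    batches <- list()
    for (pid in sample(unique(participant_id))) {
      idx <- sample(which(participant_id == pid))
      chunks <- split(idx, ceiling(seq_along(idx) / batch_size))
      batches <- c(batches, unname(chunks))
    }
    sample(batches)
  })
}

.mixed_batches <- function(n, batch_size, seed) {
  with_seed(seed, {
    idx <- sample(n)
    unname(split(idx, ceiling(seq_along(idx) / batch_size)))
  })
}

## ---- parameter initialization -------------------------------------------

.glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

nn_init <- function(family, input_dim, seq_len = NULL, hyper = list(),
                    seed = 1L) {
  with_seed(seed, {
    if (family == "mlp") {
      hidden <- hyper$hidden %||% c(64L, 32L)
      sizes <- c(input_dim, hidden, 1L)
      params <- list()
      for (l in seq_len(length(sizes) - 1L)) {
        params[[paste0("W", l)]] <- .glorot(sizes[l], sizes[l + 1L])
        params[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
      }
      list(family = "mlp", params = params, n_layers = length(sizes) - 1L,
           dropout = hyper$dropout %||% 0.3)
    } else if (family == "lstm") {
      H <- hyper$hidden %||% 16L
      b <- rep(0, 4 * H)
      b[(H + 1):(2 * H)] <- 1 # forget-gate bias
      list(family = "lstm", H = H, F_in = input_dim, T_len = seq_len,
           params = list(Wx = .glorot(input_dim, 4 * H),
                         Wh = .glorot(H, 4 * H), b = b,
                         Wo = .glorot(H, 1L), bo = 0))
    } else if (family == "transformer") {
      dm <- hyper$d_model %||% 16L
      dff <- hyper$d_ff %||% 32L
      pos <- outer(seq_len(seq_len) - 1L, seq_len(dm) - 1L,
                   function(t, j) {
                     ang <- t / 10000^(2 * (j %/% 2) / dm)
                     ifelse(j %% 2 == 0, sin(ang), cos(ang))
                   })
      list(family = "transformer", dm = dm, dff = dff, T_len = seq_len,
           pos = pos,
           params = list(We = .glorot(input_dim, dm), be = rep(0, dm),
                         Wq = .glorot(dm, dm), Wk = .glorot(dm, dm),
                         Wv = .glorot(dm, dm),
                         W1 = .glorot(dm, dff), b1 = rep(0, dff),
                         W2 = .glorot(dff, dm), b2 = rep(0, dm),
                         Wh = .glorot(dm, 1L), bh = 0))
    } else {
      stop("unknown gradient family: ", family)
    }
  })
}

## ---- forward / backward -------------------------------------------------

nn_forward <- function(net, x, train = FALSE) {
  switch(net$family,
         mlp = .mlp_forward(net, x, train),
         lstm = .lstm_forward(net, x),
         transformer = .transformer_forward(net, x))
}

nn_backward <- function(net, cache, dpred) {
  switch(net$family,
         mlp = .mlp_backward(net, cache, dpred),
         lstm = .lstm_backward(net, cache, dpred),
         transformer = .transformer_backward(net, cache, dpred))
}

.mlp_forward <- function(net, x, train) {
  p <- net$params
  a <- x
  acts <- list(a)
  masks <- list()
  for (l in seq_len(net$n_layers - 1L)) {
    z <- sweep(a %*% p[[paste0("W", l)]], 2, p[[paste0("b", l)]], "+")
    a <- relu(z)
    if (train && net$dropout > 0) {
      mask <- matrix(rbinom(length(a), 1, 1 - net$dropout),
                     nrow(a)) / (1 - net$dropout)
      a <- a * mask
      masks[[l]] <- mask
    }
    acts[[l + 1L]] <- a
  }
  L <- net$n_layers
  pred <- drop(a %*% p[[paste0("W", L)]] + p[[paste0("b", L)]])
  list(pred = pred, acts = acts, masks = masks)
}

.mlp_backward <- function(net, cache, dpred) {
  p <- net$params
  L <- net$n_layers
  g <- list()
  da <- matrix(dpred, ncol = 1) %*% t(p[[paste0("W", L)]])
  g[[paste0("W", L)]] <- t(cache$acts[[L]]) %*% matrix(dpred, ncol = 1)
  g[[paste0("b", L)]] <- sum(dpred)
  for (l in rev(seq_len(L - 1L))) {
    a <- cache$acts[[l + 1L]]
    if (length(cache$masks) >= l && !is.null(cache$masks[[l]])) {
      da <- da * cache$masks[[l]]
    }
    dz <- da * (a > 0)
    g[[paste0("W", l)]] <- t(cache$acts[[l]]) %*% dz
    g[[paste0("b", l)]] <- colSums(dz)
    da <- dz %*% t(p[[paste0("W", l)]])
  }
  g
}

.slice_t <- function(x, t) {
  matrix(x[, t, ], nrow = dim(x)[1])
}

.lstm_forward <- function(net, x) {
  p <- net$params
  B <- dim(x)[1]
  T_len <- dim(x)[2]
  H <- net$H
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  steps <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    xt <- .slice_t(x, t)
    z <- sweep(xt %*% p$Wx + h %*% p$Wh, 2, p$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- f * cc + i * gg
    tc <- tanh(cc)
    h <- o * tc
    steps[[t]] <- list(xt = xt, i = i, f = f, g = gg, o = o, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
  }
  pred <- drop(h %*% p$Wo + p$bo)
  list(pred = pred, steps = steps, h_last = h)
}

.lstm_backward <- function(net, cache, dpred) {
  p <- net$params
  H <- net$H
  B <- nrow(cache$h_last)
  dWx <- p$Wx * 0
  dWh <- p$Wh * 0
  db <- p$b * 0
  dWo <- t(cache$h_last) %*% matrix(dpred, ncol = 1)
  dbo <- sum(dpred)
  dh <- matrix(dpred, ncol = 1) %*% t(p$Wo)
  dc <- matrix(0, B, H)
  for (t in rev(seq_along(cache$steps))) {
    s <- cache$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dWx <- dWx + t(s$xt) %*% dz
    dWh <- dWh + t(s$h_prev) %*% dz
    db <- db + colSums(dz)
    dh <- dz %*% t(p$Wh)
    dc <- dc * s$f
  }
  list(Wx = dWx, Wh = dWh, b = db, Wo = dWo, bo = dbo)
}

.softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

.transformer_forward <- function(net, x) {
  p <- net$params
  B <- dim(x)[1]
  per <- vector("list", B)
  pred <- numeric(B)
  for (b in seq_len(B)) {
    X <- matrix(x[b, , ], nrow = dim(x)[2])
    E <- sweep(X %*% p$We, 2, p$be, "+") + net$pos
    Q <- E %*% p$Wq
    K <- E %*% p$Wk
    V <- E %*% p$Wv
    S <- Q %*% t(K) / sqrt(net$dm)
    A <- .softmax_rows(S)
    O <- A %*% V
    R1 <- E + O
    Z1 <- sweep(R1 %*% p$W1, 2, p$b1, "+")
    A1 <- relu(Z1)
    FF <- sweep(A1 %*% p$W2, 2, p$b2, "+")
    R2 <- R1 + FF
    pool <- colMeans(R2)
    pred[b] <- sum(pool * p$Wh) + p$bh
    per[[b]] <- list(X = X, E = E, Q = Q, K = K, V = V, A = A, R1 = R1,
                     A1 = A1, pool = pool)
  }
  list(pred = pred, per = per)
}

.transformer_backward <- function(net, cache, dpred) {
  p <- net$params
  g <- lapply(p, function(w) w * 0)
  T_len <- net$T_len
  for (b in seq_along(cache$per)) {
    cc <- cache$per[[b]]
    d <- dpred[b]
    g$Wh <- g$Wh + matrix(cc$pool * d, ncol = 1)
    g$bh <- g$bh + d
    dpool <- d * drop(p$Wh)
    dR2 <- matrix(rep(dpool / T_len, each = T_len), nrow = T_len)
    # FF branch
    dFF <- dR2
    g$b2 <- g$b2 + colSums(dFF)
    g$W2 <- g$W2 + t(cc$A1) %*% dFF
    dA1 <- dFF %*% t(p$W2)
    dZ1 <- dA1 * (cc$A1 > 0)
    g$b1 <- g$b1 + colSums(dZ1)
    g$W1 <- g$W1 + t(cc$R1) %*% dZ1
    dR1 <- dR2 + dZ1 %*% t(p$W1)
    # attention branch
    dO <- dR1
    dA <- dO %*% t(cc$V)
    dV <- t(cc$A) %*% dO
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dQ <- dS %*% cc$K / sqrt(net$dm)
    dK <- t(dS) %*% cc$Q / sqrt(net$dm)
    dE <- dR1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    g$Wq <- g$Wq + t(cc$E) %*% dQ
    g$Wk <- g$Wk + t(cc$E) %*% dK
    g$Wv <- g$Wv + t(cc$E) %*% dV
    g$We <- g$We + t(cc$X) %*% dE
    g$be <- g$be + colSums(dE)
  }
  g
}

## ---- optimizer and training loop ----------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    if (weight_decay > 0) gk <- gk + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.subset_x <- function(x, idx) {
  if (length(dim(x)) == 3L) {
    x[idx, , , drop = FALSE]
  } else {
    x[idx, , drop = FALSE]
  }
}

# One gradient pass over a list of batches; returns updated net/state.
.run_epoch <- function(net, state, x, y, batches, config, phase, lr,
                       weight_decay, dropout_seed) {
  with_seed(dropout_seed, {
    for (idx in batches) {
      fw <- nn_forward(net, .subset_x(x, idx), train = TRUE)
      dpred <- .loss_grad(fw$pred, y[idx], config, phase)
      grads <- nn_backward(net, fw, dpred)
      upd <- .adam_step(net$params, grads, state, lr, weight_decay)
      net$params <- upd$params
      state <- upd$state
    }
  })
  list(net = net, state = state)
}

nn_predict <- function(net, x) {
  nn_forward(net, x, train = FALSE)$pred
}

#' Two-phase gradient training with the variance-penalized loss
#'
#' Phase 1 iterates over participant-grouped batches with the penalized L1
#' loss of [penalized_batch_loss()]; phase 2 over conventional mixed
#' batches with plain L1. After every epoch the validation MAE is measured;
#' the parameters of the best epoch are kept, and the learning rate is
#' halved when the validation MAE has not improved for
#' `hyper$lr_patience` epochs (plateau decay). With `phase1_epochs = 0`
#' (or `weight = 0`) the loop reduces to conventional L1 training.
#'
#' @param spec a [model_spec()] of a gradient family (`mlp`, `lstm`,
#'   `transformer`).
#' @param train list `x` (matrix or n x T x F array matching the layout),
#'   `age`, `participant_id`.
#' @param val like `train`, used for checkpointing; `NULL` falls back to
#'   checkpointing on the training MAE.
#' @param config a [loss_config()].
#' @return a fitted `keydyn_model`.
#' @export
two_phase_train <- function(spec, train, val = NULL, config = loss_config()) {
  hy <- spec$hyperparameters
  x <- train$x
  # train on the centered age so the output head starts near the cohort
  # mean; the L1 scale (years) is unchanged
  y_center <- mean(train$age)
  y <- train$age - y_center
  input_dim <- tail(dim(x), 1)
  seq_len_ <- if (length(dim(x)) == 3L) dim(x)[2] else NULL
  net <- nn_init(spec$family, input_dim, seq_len_, hy, spec$seed)
  state <- .adam_init(net$params)
  lr <- hy$lr %||% 0.01
  batch_size <- hy$batch_size %||% 32L
  weight_decay <- hy$weight_decay %||% if (spec$family == "mlp") 0.001 else 0
  lr_patience <- hy$lr_patience %||% 5L
  lr_factor <- hy$lr_factor %||% 0.5

  eval_mae <- function(net) {
    d <- if (is.null(val)) train else val
    mean(abs(nn_predict(net, d$x) + y_center - d$age))
  }
  best <- list(params = net$params, mae = eval_mae(net))
  stall <- 0L
  epoch_seed <- spec$seed * 1000L

  run_phase <- function(phase, n_epochs) {
    for (e in seq_len(n_epochs)) {
      es <- (epoch_seed + phase * 500L + e) %% .Machine$integer.max
      batches <- if (phase == 1L) {
        participant_batches(train$participant_id, batch_size, es)
      } else {
        .mixed_batches(length(y), batch_size, es)
      }
      res <- .run_epoch(net, state, x, y, batches, config, phase, lr,
                        weight_decay, es + 1L)
      net <<- res$net
      state <<- res$state
      mae <- eval_mae(net)
      if (mae < best$mae - 1e-6) {
        best <<- list(params = net$params, mae = mae)
        stall <<- 0L
      } else {
        stall <<- stall + 1L
        if (stall >= lr_patience) {
          lr <<- max(lr * lr_factor, 1e-4)
          stall <<- 0L
        }
      }
    }
  }
  run_phase(1L, config$phase1_epochs)
  run_phase(2L, config$phase2_epochs)

  net$params <- best$params
  structure(list(spec = spec, family = spec$family, net = net,
                 y_center = y_center, val_mae = best$mae,
                 loss_config = config),
            class = "keydyn_model")
}
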