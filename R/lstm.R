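#' LSTM hyperparameters
#'
#' Architecture: one LSTM layer over the 31-frame window, dropout, one dense
#' hidden layer with rectified-linear activation, and a single sigmoid
#' output unit trained with class-weighted binary cross-entropy. The grids
#' explored for this task were batch size (32, 64, 128), LSTM and dense
#' nodes (25, 50, 75, 100), dropout (0.3, 0.4, 0.5) and class weighting
#' (1:2, 1:5, 1:10, 1:20); the defaults are the best configuration found:
#' batch 64, 100 LSTM nodes, 50 dense nodes, dropout 0.4, weighting 1:2.
#'
#' Optimiser settings (Adam, learning rate, epoch budget, early-stopping
#' patience) are implementation choices and fully configurable.
#'
#' @param batch_size Minibatch size.
#' @param lstm_nodes Hidden units in the LSTM layer.
#' @param dense_nodes Hidden units in the dense layer.
#' @param dropout Dropout fraction applied to the LSTM output, in `[0, 1)`.
#' @param class_weight_ratio Loss weight of the positive class.
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam learning rate.
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); only active when `validation_fraction > 0`.
#' @param validation_fraction Fraction of windows held out for
#'   early stopping (0 disables).
#' @return An object of class `lstm_hyperparams`.
#' @export
lstm_hyperparams <- function(batch_size = 64, lstm_nodes = 100,
                             dense_nodes = 50, dropout = 0.4,
                             class_weight_ratio = 2, epochs = 30,
                             learning_rate = 1e-3, seed = 1L,
                             patience = 5, validation_fraction = 0.1) {
  stopifnot(batch_size >= 1, lstm_nodes >= 1, dense_nodes >= 1,
            dropout >= 0, dropout < 1, class_weight_ratio > 0,
            epochs >= 1, learning_rate > 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 lstm_nodes = as.integer(lstm_nodes),
                 dense_nodes = as.integer(dense_nodes),
                 dropout = dropout, class_weight_ratio = class_weight_ratio,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), patience = as.integer(patience),
                 validation_fraction = validation_fraction),
            class = "lstm_hyperparams")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias row-vector to every row of Z (column-major recycling)
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

lstm_init_params <- function(n_in, H, D) {
  glorot <- function(fin, fout) {
    s <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -s, s), fin, fout)
  }
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1           # forget-gate bias (order i, f, o, g)
  list(Wx = glorot(n_in, 4 * H), Wh = glorot(H, 4 * H), b = b,
       W1 = glorot(H, D), b1 = numeric(D),
       W2 = glorot(D, 1), b2 = 0,
       H = H, D = D, n_in = n_in)
}

# forward pass over the 31-frame sequence for one batch; `rows` is a
# B x 31 matrix of feature-row indices. Gate column order is [i, f, o, g]
# so the three sigmoid gates share one exp() call.
lstm_forward_seq <- function(par, feats, rows, keep_cache = TRUE) {
  B <- nrow(rows)
  H <- par$H
  i_ix <- seq_len(H); f_ix <- H + i_ix; o_ix <- 2 * H + i_ix
  g_ix <- 3 * H + i_ix
  sig_ix <- seq_len(3 * H)
  Bmat <- matrix(par$b, B, 4 * H, byrow = TRUE)
  Hs <- matrix(0, B, H)
  Cs <- matrix(0, B, H)
  Tn <- ncol(rows)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Xt <- feats[rows[, t], , drop = FALSE]
    Z <- Xt %*% par$Wx + Hs %*% par$Wh + Bmat
    S <- sigmoid(Z[, sig_ix, drop = FALSE])
    gg <- tanh(Z[, g_ix, drop = FALSE])
    gi <- S[, i_ix, drop = FALSE]
    gf <- S[, f_ix, drop = FALSE]
    go <- S[, o_ix, drop = FALSE]
    Cprev <- Cs
    Cs <- gf * Cprev + gi * gg
    tC <- tanh(Cs)
    Hprev <- Hs
    Hs <- go * tC
    if (keep_cache) {
      cache[[t]] <- list(Xt = Xt, i = gi, f = gf, g = gg, o = go,
                         Cprev = Cprev, tC = tC, Hprev = Hprev)
    }
  }
  list(H = Hs, cache = cache)
}

# head: dropout -> dense ReLU -> sigmoid unit
lstm_head_forward <- function(par, Hout, drop_mask = NULL) {
  Hd <- if (is.null(drop_mask)) Hout else Hout * drop_mask
  A1 <- add_bias(Hd %*% par$W1, par$b1)
  R1 <- pmax(A1, 0)
  P <- sigmoid(drop(R1 %*% par$W2) + par$b2)
  list(Hd = Hd, A1 = A1, R1 = R1, P = P)
}

lstm_weighted_bce <- function(p, y, ratio) {
  eps <- 1e-12
  w <- ifelse(y == 1, ratio, 1)
  mean(w * -(y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

# full backward pass; dS is the gradient at the output logit (length B)
lstm_backward <- function(par, fw, head, dS) {
  B <- length(dS)
  dW2 <- crossprod(head$R1, dS)
  db2 <- sum(dS)
  dR1 <- tcrossprod(dS, drop(par$W2))          # B x D
  dA1 <- dR1 * (head$A1 > 0)
  dW1 <- crossprod(head$Hd, dA1)
  db1 <- colSums(dA1)
  dHd <- tcrossprod(dA1, par$W1)               # B x H
  dH <- if (is.null(fw$drop_mask)) dHd else dHd * fw$drop_mask

  H <- par$H
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dC <- matrix(0, B, H)
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    do_ <- dH * cc$tC
    dC <- dC + dH * cc$o * (1 - cc$tC^2)
    di <- dC * cc$g
    df <- dC * cc$Cprev
    dg <- dC * cc$i
    # gate order [i, f, o, g], matching the forward pass
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$Xt, dZ)
    dWh <- dWh + crossprod(cc$Hprev, dZ)
    db <- db + colSums(dZ)
    dH <- tcrossprod(dZ, par$Wh)
    dC <- dC * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

#' Train the windowed LSTM classifier
#'
#' Trains the LSTM -> dropout -> dense(ReLU) -> sigmoid architecture on a
#' windowed dataset with class-weighted binary cross-entropy, using Adam
#' with minibatch shuffling. Training is implemented natively in R with
#' batched BLAS matrix operations (forward pass, backpropagation through
#' time, Adam). A fixed `hp$seed` makes initialisation, shuffling and
#' dropout -- and hence the trained model -- fully reproducible.
#'
#' When `hp$validation_fraction > 0` a random window subset is held out; the
#' parameters with the best held-out loss are kept and training stops early
#' after `hp$patience` epochs without improvement.
#'
#' @param dataset An `fs_windows` dataset from [make_windows()] /
#'   [combine_windows()] containing both classes.
#' @param hp An [lstm_hyperparams()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `fs_lstm_model`.
#' @export
train_lstm <- function(dataset, hp = lstm_hyperparams(), verbose = FALSE) {
  stopifnot(inherits(dataset, "fs_windows"), inherits(hp, "lstm_hyperparams"))
  y_all <- dataset$labels
  if (length(y_all) == 0L || length(unique(y_all)) < 2L)
    stop("training data must be non-empty and contain both classes",
         call. = FALSE)
  set.seed(hp$seed)
  n_in <- ncol(dataset$features)
  par <- lstm_init_params(n_in, hp$lstm_nodes, hp$dense_nodes)
  state <- list(t = 0L,
                m = lapply(par[c("Wx", "Wh", "b", "W1", "b1", "W2", "b2")],
                           function(x) x * 0),
                v = lapply(par[c("Wx", "Wh", "b", "W1", "b1", "W2", "b2")],
                           function(x) x * 0))

  N <- length(dataset$starts)
  idx_all <- seq_len(N)
  val_idx <- integer(0)
  if (hp$validation_fraction > 0) {
    nval <- floor(hp$validation_fraction * N)
    if (nval >= 2L) val_idx <- sample(idx_all, nval)
  }
  train_idx <- setdiff(idx_all, val_idx)
  if (length(unique(y_all[train_idx])) < 2L) {
    val_idx <- integer(0)
    train_idx <- idx_all
  }

  best <- list(loss = Inf, par = par)
  stall <- 0L
  p_drop <- hp$dropout
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / hp$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      bidx <- ord[((bi - 1L) * hp$batch_size + 1L):
                    min(bi * hp$batch_size, length(ord))]
      rows <- outer(dataset$starts[bidx], 0:30, "+")
      y <- y_all[bidx]
      B <- length(bidx)
      fw <- lstm_forward_seq(par, dataset$features, rows)
      if (p_drop > 0) {
        fw$drop_mask <- matrix(
          (stats::runif(B * par$H) >= p_drop) / (1 - p_drop), B, par$H)
      } else fw$drop_mask <- NULL
      head <- lstm_head_forward(par, fw$H, fw$drop_mask)
      w <- ifelse(y == 1L, hp$class_weight_ratio, 1)
      ep_loss <- ep_loss + lstm_weighted_bce(head$P, y, hp$class_weight_ratio) * B
      dS <- w * (head$P - y) / B
      grads <- lstm_backward(par, fw, head, dS)
      upd <- adam_step(par, grads, state, hp$learning_rate)
      par <- upd$par
      state <- upd$state
    }
    ep_loss <- ep_loss / length(ord)
    if (length(val_idx)) {
      vp <- lstm_prob_for(par, dataset, val_idx)
      vloss <- lstm_weighted_bce(vp, y_all[val_idx], hp$class_weight_ratio)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch, ep_loss, vloss))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, par = par)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= hp$patience) break
      }
    } else {
      if (verbose) message(sprintf("epoch %d: train %.4f", epoch, ep_loss))
      best <- list(loss = ep_loss, par = par)
    }
  }
  if (length(val_idx) == 0L) best$par <- par
  structure(list(params = best$par, hp = hp, n_in = n_in),
            class = "fs_lstm_model")
}

lstm_prob_for <- function(par, dataset, idx, chunk = 2048L) {
  out <- numeric(length(idx))
  for (s in seq(1L, length(idx), by = chunk)) {
    sel <- idx[s:min(s + chunk - 1L, length(idx))]
    rows <- outer(dataset$starts[sel], 0:30, "+")
    fw <- lstm_forward_seq(par, dataset$features, rows, keep_cache = FALSE)
    out[s:(s + length(sel) - 1L)] <- lstm_head_forward(par, fw$H)$P
  }
  out
}

#' Class-1 probabilities for every window of a dataset
#'
#' @param model An `fs_lstm_model`.
#' @param dataset An `fs_windows` dataset.
#' @return Numeric vector of probabilities, one per window.
#' @export
lstm_predict_prob <- function(model, dataset) {
  stopifnot(inherits(model, "fs_lstm_model"), inherits(dataset, "fs_windows"))
  if (ncol(dataset$features) != model$n_in)
    stop("feature dimension does not match the trained model", call. = FALSE)
  lstm_prob_for(model$params, dataset, seq_along(dataset$starts))
}
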