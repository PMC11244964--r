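# Compact single-layer LSTM regression network, trained with truncated BPTT
# and Adam, in plain matrix code. Deliberately minimal: one layer, scalar
# output, MSE loss, gradient clipping. Deterministic given the caller's RNG
# state (initialization and update order are the only stochastic parts and
# both run under the caller's seed).

lstm_init <- function(input_dim, hidden) {
  gs <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
  H <- hidden
  p <- list(
    W = gs(4 * H, input_dim, 1 / sqrt(input_dim)),  # input weights (i,f,o,g)
    U = gs(4 * H, H, 1 / sqrt(H)),                  # recurrent weights
    b = rep(0, 4 * H),
    V = gs(1, H, 1 / sqrt(H)),                      # readout
    c0 = 0)
  p$b[(H + 1):(2 * H)] <- 1   # forget-gate bias init
  p
}

sigm <- function(x) 1 / (1 + exp(-x))

# Forward pass over one segment. X: T x D. Returns predictions and caches.
lstm_forward <- function(p, X) {
  H <- length(p$b) / 4
  Tn <- nrow(X)
  i_ix <- 1:H; f_ix <- (H + 1):(2 * H); o_ix <- (2 * H + 1):(3 * H)
  g_ix <- (3 * H + 1):(4 * H)
  ZW <- p$W %*% t(X)   # 4H x T
  hs <- matrix(0, H, Tn); cs <- matrix(0, H, Tn)
  gates <- matrix(0, 4 * H, Tn)
  h <- rep(0, H); cc <- rep(0, H)
  for (t in seq_len(Tn)) {
    z <- ZW[, t] + p$U %*% h + p$b
    i <- sigm(z[i_ix]); f <- sigm(z[f_ix]); o <- sigm(z[o_ix])
    g <- tanh(z[g_ix])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    gates[, t] <- c(i, f, o, g)
    cs[, t] <- cc; hs[, t] <- h
  }
  yhat <- as.numeric(p$V %*% hs) + p$c0
  list(yhat = yhat, hs = hs, cs = cs, gates = gates)
}

# Backward pass; returns gradients for one segment (mean squared error loss).
lstm_backward <- function(p, X, y, fw) {
  H <- length(p$b) / 4
  Tn <- nrow(X)
  i_ix <- 1:H; f_ix <- (H + 1):(2 * H); o_ix <- (2 * H + 1):(3 * H)
  g_ix <- (3 * H + 1):(4 * H)
  dy <- 2 * (fw$yhat - y) / Tn           # dL/dyhat
  gV <- dy %*% t(fw$hs)                  # 1 x H
  gc0 <- sum(dy)
  gW <- matrix(0, 4 * H, ncol(X)); gU <- matrix(0, 4 * H, H)
  gb <- rep(0, 4 * H)
  dh_next <- rep(0, H); dc_next <- rep(0, H)
  for (t in rev(seq_len(Tn))) {
    i <- fw$gates[i_ix, t]; f <- fw$gates[f_ix, t]
    o <- fw$gates[o_ix, t]; g <- fw$gates[g_ix, t]
    cc <- fw$cs[, t]
    c_prev <- if (t > 1) fw$cs[, t - 1] else rep(0, H)
    h_prev <- if (t > 1) fw$hs[, t - 1] else rep(0, H)
    dh <- as.numeric(t(p$V) * dy[t]) + dh_next
    tc <- tanh(cc)
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g; df <- dc * c_prev; dg <- dc * i
    dz <- c(di * i * (1 - i), df * f * (1 - f), do_ * o * (1 - o),
            dg * (1 - g^2))
    gW <- gW + tcrossprod(dz, X[t, ])
    gU <- gU + tcrossprod(dz, h_prev)
    gb <- gb + dz
    dh_next <- as.numeric(crossprod(p$U, dz))
    dc_next <- dc * f
  }
  list(W = gW, U = gU, b = gb, V = gV, c0 = gc0)
}

# Train on a list of segments (each T x D) with matching target lists.
lstm_train <- function(X_segs, y_segs, hidden = 64, epochs = 20, lr = 0.01,
                       clip = 5, weight_decay = 0.05) {
  p <- lstm_init(ncol(X_segs[[1]]), hidden)
  mom <- lapply(p, function(x) x * 0)
  vel <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(length(X_segs))   # under the caller's seeded RNG
    for (s in ord) {
      fw <- lstm_forward(p, X_segs[[s]])
      gr <- lstm_backward(p, X_segs[[s]], y_segs[[s]], fw)
      step <- step + 1
      for (nm in names(p)) {
        g <- gr[[nm]]
        if (nm %in% c("W", "U", "V")) g <- g + weight_decay * p[[nm]]
        gn <- sqrt(sum(g^2))
        if (is.finite(gn) && gn > clip) g <- g * clip / gn
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  p
}

lstm_predict <- function(p, X) lstm_forward(p, X)$yhat
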