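# LSTM autoencoder. The window is averaged down to cp2/8 time steps; a
# single-layer LSTM encoder reads the sequence and its final hidden state
# is projected to the latent vector. The decoder feeds the latent vector as
# the input of every step of a second LSTM, projects each hidden state to a
# scalar, and a final dense layer maps the step sequence back to the input
# length. Gate weights are stored as one [in+hidden, 4*hidden] matrix in
# gate order i, f, g, o.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(n_in, n_hid) {
  s <- sqrt(1 / n_hid)
  list(W = matrix(stats::runif((n_in + n_hid) * 4L * n_hid, -s, s),
                  n_in + n_hid, 4L * n_hid),
       b = numeric(4L * n_hid))
}

#' Build an untrained LSTM autoencoder
#'
#' See [build_cnn_ae()] for the shared contract: `encode` produces a
#' `latent_dim` vector per window, `decode` reconstructs the input length.
#'
#' @param cfg A [ae_config()] with `arch = "lstm"`.
#' @return Untrained model of class `pp_ae`.
#' @export
build_lstm_ae <- function(cfg) {
  stopifnot(inherits(cfg, "pp_ae_config"))
  set.seed(cfg$seed)
  H <- cfg$lstm_hidden
  Tn <- max(2L, cfg$cp2 %/% 8L)
  params <- list(
    enc = lstm_init(1L, H),
    Lz = dense_init(H, cfg$latent_dim),
    dec = lstm_init(cfg$latent_dim, H),
    Ly = dense_init(H, 1L),
    L3 = dense_init(Tn, cfg$input_len)
  )
  structure(list(cfg = cfg, params = params, n_steps = Tn),
            class = c("pp_ae_lstm", "pp_ae"))
}

# Average-pool each row of X [B, input_len] down to Tn steps.
pool_steps <- function(X, Tn) {
  n <- ncol(X)
  edges <- floor(seq(0, n, length.out = Tn + 1L))
  sapply(seq_len(Tn), function(i) {
    idx <- (edges[i] + 1L):edges[i + 1L]
    rowMeans(X[, idx, drop = FALSE])
  })
}

lstm_run <- function(inputs, W, b, H) {
  # inputs: list of T matrices [B, n_in]
  Tn <- length(inputs)
  B <- nrow(inputs[[1L]])
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xh <- cbind(inputs[[t]], h)
    pre <- sweep(xh %*% W, 2L, b, "+")
    i_g <- sigmoid(pre[, seq_len(H), drop = FALSE])
    f_g <- sigmoid(pre[, H + seq_len(H), drop = FALSE])
    g_g <- tanh(pre[, 2L * H + seq_len(H), drop = FALSE])
    o_g <- sigmoid(pre[, 3L * H + seq_len(H), drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h <- o_g * tc
    cache[[t]] <- list(xh = xh, i = i_g, f = f_g, g = g_g, o = o_g,
                       c = cc, c_prev = c_prev, tc = tc, h = h)
  }
  list(h = h, cache = cache)
}

# Backpropagation through time. dh_steps: list of gradients on each step's
# hidden state (NULL entries allowed); returns dW, db and gradients on the
# step inputs.
lstm_bptt <- function(cache, W, H, dh_steps, n_in) {
  Tn <- length(cache)
  B <- nrow(cache[[1L]]$h)
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dx <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    s <- cache[[t]]
    dh <- dh_next
    if (!is.null(dh_steps[[t]])) dh <- dh + dh_steps[[t]]
    do_ <- dh * s$tc
    dc <- dc_next + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dc_next <- dc * s$f
    dpre <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
    dW <- dW + crossprod(s$xh, dpre)
    db <- db + colSums(dpre)
    dxh <- dpre %*% t(W)
    dx[[t]] <- dxh[, seq_len(n_in), drop = FALSE]
    dh_next <- dxh[, n_in + seq_len(H), drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

lstm_forward <- function(model, X) {
  p <- model$params; cfg <- model$cfg
  H <- cfg$lstm_hidden; Tn <- model$n_steps
  B <- nrow(X)
  steps <- pool_steps(X, Tn)
  enc_in <- lapply(seq_len(Tn), function(t) steps[, t, drop = FALSE])
  enc <- lstm_run(enc_in, p$enc$W, p$enc$b, H)
  z <- sweep(enc$h %*% p$Lz$W, 2L, p$Lz$b, "+")
  dec_in <- rep(list(z), Tn)
  dec <- lstm_run(dec_in, p$dec$W, p$dec$b, H)
  ys <- sapply(seq_len(Tn), function(t) {
    drop(sweep(dec$cache[[t]]$h %*% p$Ly$W, 2L, p$Ly$b, "+"))
  })
  if (B == 1L) ys <- matrix(ys, nrow = 1L)
  recon <- sweep(ys %*% p$L3$W, 2L, p$L3$b, "+")
  list(latent = z, recon = recon,
       cache = list(X = X, steps = steps, enc = enc, z = z, dec = dec,
                    ys = ys))
}

lstm_backward <- function(model, cache, dRecon) {
  p <- model$params; cfg <- model$cfg
  H <- cfg$lstm_hidden; Tn <- model$n_steps
  B <- nrow(dRecon)
  g <- list()
  g$L3 <- list(W = crossprod(cache$ys, dRecon), b = colSums(dRecon))
  dys <- dRecon %*% t(p$L3$W)                  # [B, Tn]
  dh_steps <- vector("list", Tn)
  dLyW <- matrix(0, H, 1L); dLyb <- 0
  for (t in seq_len(Tn)) {
    dyt <- dys[, t, drop = FALSE]
    ht <- cache$dec$cache[[t]]$h
    dLyW <- dLyW + crossprod(ht, dyt)
    dLyb <- dLyb + sum(dyt)
    dh_steps[[t]] <- dyt %*% t(p$Ly$W)
  }
  g$Ly <- list(W = dLyW, b = dLyb)
  bd <- lstm_bptt(cache$dec$cache, p$dec$W, H, dh_steps, cfg$latent_dim)
  g$dec <- list(W = bd$dW, b = bd$db)
  dz <- Reduce(`+`, bd$dx)
  g$Lz <- list(W = crossprod(cache$enc$h, dz), b = colSums(dz))
  dh_enc <- vector("list", Tn)
  dh_enc[[Tn]] <- dz %*% t(p$Lz$W)
  be <- lstm_bptt(cache$enc$cache, p$enc$W, H, dh_enc, 1L)
  g$enc <- list(W = be$dW, b = be$db)
  g
}
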