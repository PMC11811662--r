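ae_forward <- function(model, X) {
  if (inherits(model, "pp_ae_cnn")) cnn_forward(model, X)
  else lstm_forward(model, X)
}

ae_backward <- function(model, cache, dRecon) {
  if (inherits(model, "pp_ae_cnn")) cnn_backward(model, cache, dRecon)
  else lstm_backward(model, cache, dRecon)
}

# Adam over a nested list of parameter blocks.
adam_state <- function(params) {
  lapply(params, function(p) lapply(p, function(w) {
    list(m = array(0, dim = dim_or_len(w)), v = array(0, dim = dim_or_len(w)))
  }))
}

dim_or_len <- function(w) if (is.matrix(w)) dim(w) else length(w)

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (blk in names(params)) {
    for (w in names(params[[blk]])) {
      gw <- grads[[blk]][[w]]
      st <- state[[blk]][[w]]
      st$m <- beta1 * st$m + (1 - beta1) * gw
      st$v <- beta2 * st$v + (1 - beta2) * gw^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[blk]][[w]] <- params[[blk]][[w]] - lr * mhat / (sqrt(vhat) + eps)
      state[[blk]][[w]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train an autoencoder on normalized windows
#'
#' Minimizes mean-squared reconstruction error with the Adam optimizer
#' (batch size, epochs and learning rate from the model's config). Batch
#' order is drawn from the config seed, so training is fully deterministic.
#'
#' @param model An untrained model from [build_cnn_ae()] or
#'   [build_lstm_ae()].
#' @param windows Matrix of training windows, one per row, already
#'   normalized (see [normalize_windows()]); at least `batch_size` rows.
#' @return Object of class `pp_encoder`: the trained model plus
#'   `loss_history` (per-epoch mean reconstruction MSE).
#' @export
train_ae <- function(model, windows) {
  stopifnot(inherits(model, "pp_ae"))
  cfg <- model$cfg
  X <- as.matrix(windows)
  if (ncol(X) != cfg$input_len) {
    stop(sprintf("windows have %d samples; model expects %d", ncol(X),
                 cfg$input_len))
  }
  n <- nrow(X)
  if (n < cfg$batch_size) {
    stop(sprintf("need at least batch_size = %d windows, got %d",
                 cfg$batch_size, n))
  }
  set.seed(cfg$seed + 1L)
  state <- adam_state(model$params)
  loss_history <- numeric(cfg$epochs)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = cfg$batch_size)
    ep_loss <- 0; ep_count <- 0L
    for (s0 in starts) {
      idx <- ord[s0:min(n, s0 + cfg$batch_size - 1L)]
      Xb <- X[idx, , drop = FALSE]
      fw <- ae_forward(model, Xb)
      err <- fw$recon - Xb
      loss <- mean(err^2)
      if (!is.finite(loss)) stop("training diverged: non-finite loss")
      ep_loss <- ep_loss + loss * length(idx)
      ep_count <- ep_count + length(idx)
      dRecon <- 2 * err / length(err)
      grads <- ae_backward(model, fw$cache, dRecon)
      step <- step + 1L
      upd <- adam_step(model$params, grads, state, cfg$learning_rate, step)
      model$params <- upd$params
      state <- upd$state
    }
    loss_history[ep] <- ep_loss / ep_count
  }
  structure(list(model = model, cfg = cfg, loss_history = loss_history),
            class = "pp_encoder")
}

#' Encode windows to latent features
#'
#' @param enc A trained `pp_encoder` from [train_ae()].
#' @param windows Matrix of normalized windows (same length as training).
#' @return Matrix `[n, latent_dim]` of latent features.
#' @export
ae_encode <- function(enc, windows) {
  stopifnot(inherits(enc, "pp_encoder"))
  X <- as.matrix(windows)
  if (ncol(X) != enc$cfg$input_len) {
    stop(sprintf("windows have %d samples; encoder expects %d", ncol(X),
                 enc$cfg$input_len))
  }
  ae_forward(enc$model, X)$latent
}

#' Reconstruct windows through the autoencoder
#' @param enc A trained `pp_encoder`.
#' @param windows Matrix of normalized windows.
#' @return Matrix of reconstructions, same shape as `windows`.
#' @export
ae_reconstruct <- function(enc, windows) {
  stopifnot(inherits(enc, "pp_encoder"))
  ae_forward(enc$model, as.matrix(windows))$recon
}

# ---- pipeline-level automatic feature extraction ------------------------

# Window matrices for AE consumption: per modality a list with the window
# matrix (resampled to a fixed length), window metadata, and for EMG one
# matrix per channel. RR windows come from the derived respiration signal.
ae_window_matrices <- function(rec, window_len, cfg) {
  res_len <- cfg$autoencoder$resample_len
  step <- if (is.null(cfg$features$step_s)) window_len else cfg$features$step_s
  out <- list()
  grab <- function(sig, len_out) {
    wins <- sliding_windows(sig, window_len, step)
    if (!length(wins)) return(NULL)
    X <- t(vapply(wins, function(w) resample_linear(w$samples, len_out),
                  numeric(len_out)))
    list(X = X,
         t_start = vapply(wins, `[[`, numeric(1), "t_start"),
         t_end = vapply(wins, `[[`, numeric(1), "t_end"))
  }
  if ("ecg" %in% names(rec$channels)) {
    out$ecg <- grab(rec$channels$ecg[[1L]], res_len[["ecg"]])
  }
  if ("emg" %in% names(rec$channels)) {
    per_ch <- lapply(rec$channels$emg, grab, len_out = res_len[["emg"]])
    if (!any(vapply(per_ch, is.null, logical(1)))) {
      out$emg <- list(channels = lapply(per_ch, `[[`, "X"),
                      t_start = per_ch[[1L]]$t_start,
                      t_end = per_ch[[1L]]$t_end)
    }
  }
  if ("eda" %in% names(rec$channels)) {
    out$eda <- grab(rec$channels$eda[[1L]], res_len[["eda"]])
  }
  if ("ppg" %in% names(rec$channels)) {
    resp <- tryCatch(derive_respiration(rec$channels$ppg[[1L]]),
                     error = function(e) NULL)
    if (!is.null(resp)) out$rr <- grab(resp, res_len[["rr"]])
  }
  out
}

#' Train per-modality autoencoders on a set of preprocessed recordings
#'
#' One autoencoder per modality with latent size 32 (ECG, EDA, RR) and one
#' autoencoder per EMG channel with latent size 6 (30 across the montage).
#' Training is unsupervised on all windows of the supplied recordings —
#' pass only training-fold subjects to keep subject-level evaluation
#' honest.
#'
#' @param recs List of preprocessed [pp_recording()]s.
#' @param window_len Window length in seconds.
#' @param cfg Configuration list (`autoencoder` section).
#' @param seed Integer seed.
#' @return Named list of trained encoders per modality (EMG entry is a list
#'   of 5 per-channel encoders).
#' @export
train_modality_encoders <- function(recs, window_len = 10,
                                    cfg = default_config(), seed = 0L) {
  acfg <- cfg$autoencoder
  mats <- lapply(recs, ae_window_matrices, window_len = window_len, cfg = cfg)
  norm <- acfg$normalization
  enc <- list()
  build <- function(input_len, latent, sd_seed) {
    c0 <- ae_config(input_len, latent, arch = acfg$arch,
                    epochs = acfg$epochs, batch_size = acfg$batch_size,
                    learning_rate = acfg$learning_rate, seed = sd_seed,
                    cnn_channels = acfg$cnn_channels, kernel = acfg$cnn_kernel,
                    lstm_hidden = acfg$lstm_hidden)
    if (acfg$arch == "cnn") build_cnn_ae(c0) else build_lstm_ae(c0)
  }
  for (mod in c("ecg", "eda", "rr")) {
    Xs <- lapply(mats, function(m) if (is.null(m[[mod]])) NULL else m[[mod]]$X)
    Xs <- Xs[!vapply(Xs, is.null, logical(1))]
    if (!length(Xs)) next
    X <- normalize_windows(do.call(rbind, Xs), norm)
    model <- build(ncol(X), acfg$latent_dim, seed + match(mod, MODALITIES))
    enc[[mod]] <- train_ae(model, X)
  }
  emg_ok <- vapply(mats, function(m) !is.null(m$emg), logical(1))
  if (any(emg_ok)) {
    n_ch <- length(mats[[which(emg_ok)[1L]]]$emg$channels)
    enc$emg <- lapply(seq_len(n_ch), function(ci) {
      X <- do.call(rbind, lapply(mats[emg_ok],
                                 function(m) m$emg$channels[[ci]]))
      X <- normalize_windows(X, norm)
      model <- build(ncol(X), acfg$emg_latent_per_channel,
                     seed + 10L + ci)
      train_ae(model, X)
    })
  }
  enc
}

#' Extract automatic (autoencoder) features from a recording
#'
#' Applies trained per-modality encoders to the recording's windows,
#' producing 32 latent features for ECG, EDA and RR and 6 per EMG channel
#' (30 over the montage; 126 in total across the 4 modalities).
#'
#' @param encoders Output of [train_modality_encoders()].
#' @param rec A preprocessed [pp_recording()].
#' @param window_len Window length in seconds.
#' @param cfg Configuration list.
#' @return A `pp_features` list of per-modality data.frames with
#'   `feature_source` `"auto_cnn"` or `"auto_lstm"`.
#' @export
extract_auto_features <- function(encoders, rec, window_len = 10,
                                  cfg = default_config()) {
  mats <- ae_window_matrices(rec, window_len, cfg)
  norm <- cfg$autoencoder$normalization
  src <- paste0("auto_", cfg$autoencoder$arch)
  out <- list()
  for (mod in c("ecg", "eda", "rr")) {
    if (is.null(encoders[[mod]]) || is.null(mats[[mod]])) next
    Z <- ae_encode(encoders[[mod]], normalize_windows(mats[[mod]]$X, norm))
    colnames(Z) <- paste0(mod, "_ae", seq_len(ncol(Z)))
    out[[mod]] <- data.frame(
      subject_id = rec$subject_id, modality = mod,
      t_start = mats[[mod]]$t_start, t_end = mats[[mod]]$t_end,
      window_len = window_len, feature_source = src, Z,
      check.names = FALSE, row.names = NULL)
  }
  if (!is.null(encoders$emg) && !is.null(mats$emg)) {
    Zs <- lapply(seq_along(encoders$emg), function(ci) {
      Z <- ae_encode(encoders$emg[[ci]],
                     normalize_windows(mats$emg$channels[[ci]], norm))
      colnames(Z) <- paste0("emg", ci, "_ae", seq_len(ncol(Z)))
      Z
    })
    Z <- do.call(cbind, Zs)
    out$emg <- data.frame(
      subject_id = rec$subject_id, modality = "emg",
      t_start = mats$emg$t_start, t_end = mats$emg$t_end,
      window_len = window_len, feature_source = src, Z,
      check.names = FALSE, row.names = NULL)
  }
  structure(out[intersect(MODALITIES, names(out))],
            class = c("pp_features", "list"))
}
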