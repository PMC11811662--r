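#' Closest power of two
#'
#' The power of two minimizing the absolute distance to `n`; ties are broken
#' downward. Used to size the autoencoder's internal grid so the network
#' scales to arbitrary window lengths.
#'
#' @param n Positive integer.
#' @return Integer power of two.
#' @export
closest_power_of_two <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive integer")
  }
  lo <- 2^floor(log2(n))
  hi <- 2^ceiling(log2(n))
  if (n - lo <= hi - n) as.integer(lo) else as.integer(hi)
}

#' Autoencoder configuration
#'
#' @param input_len Window length in samples fed to the network.
#' @param latent_dim Size of the latent feature vector (32 for ECG/EDA/RR,
#'   6 per EMG channel).
#' @param arch `"cnn"` or `"lstm"`.
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 10).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed controlling initialization and batch order.
#' @param cnn_channels Channel widths of the three convolutional layers.
#' @param kernel Convolution kernel size (odd; stride is fixed at 2).
#' @param lstm_hidden Hidden size of the LSTM encoder/decoder.
#' @return List of class `pp_ae_config` with the derived `cp2` field.
#' @export
ae_config <- function(input_len, latent_dim = 32L,
                      arch = c("cnn", "lstm"),
                      epochs = 100L, batch_size = 10L, learning_rate = 1e-3,
                      seed = 0L, cnn_channels = c(16L, 32L, 64L),
                      kernel = 3L, lstm_hidden = 64L) {
  arch <- match.arg(arch)
  input_len <- as.integer(input_len)
  cp2 <- closest_power_of_two(input_len)
  if (cp2 < 8L) stop("input too short: internal grid must be at least 8 samples")
  if (latent_dim >= cp2) {
    stop(sprintf("latent_dim (%d) must be smaller than the internal grid cp2 (%d)",
                 latent_dim, cp2))
  }
  structure(
    list(input_len = input_len, cp2 = cp2, latent_dim = as.integer(latent_dim),
         arch = arch, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         seed = as.integer(seed), cnn_channels = as.integer(cnn_channels),
         kernel = as.integer(kernel), lstm_hidden = as.integer(lstm_hidden)),
    class = "pp_ae_config"
  )
}

#' Normalize autoencoder input windows
#'
#' @param X Matrix, one window per row.
#' @param method `"minmax"` (per-window to `[0,1]`; constant windows map to
#'   0) or `"zscore"` (per-window standardization).
#' @return Normalized matrix of the same shape.
#' @export
normalize_windows <- function(X, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  t(apply(X, 1L, function(r) {
    if (method == "minmax") {
      rng <- max(r) - min(r)
      if (rng == 0) rep(0, length(r)) else (r - min(r)) / rng
    } else {
      s <- stats::sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }
  }))
}

# Linear resampling of a vector to a fixed length.
resample_linear <- function(x, len_out) {
  if (length(x) == len_out) return(as.numeric(x))
  stats::approx(seq_along(x), x, n = len_out)$y
}
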