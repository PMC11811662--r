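#' Names of the per-channel EMG features, in column order
#' @return Character vector of 14 names.
#' @export
emg_feature_names <- function() {
  c("peak", "p2p_mean", "rms", "masd2", "masd1", "masd2_norm", "masd1_norm",
    "local_min_mean", "local_max_mean", "mean_abs",
    "variance", "sd", "range", "iqr")
}

#' Amplitude and variability features of one EMG window
#'
#' The 10 amplitude features: peak (max absolute value), mean peak-to-peak
#' amplitude over short sub-frames, RMS, mean absolute second and first
#' differences (raw and on the z-scored window), means of local minima and
#' local maxima, and mean absolute value. The 4 variability features:
#' variance, SD, range, IQR. A constant window has no local extrema; the
#' extremum means then fall back to the constant value, and the normalized
#' difference features are 0.
#'
#' @param x Numeric vector: one window of one preprocessed EMG channel.
#' @param fs Sampling rate in Hz (used to form the peak-to-peak sub-frames).
#' @param p2p_frame_s Sub-frame length in seconds for the peak-to-peak mean
#'   (default 0.5 s).
#' @return Named numeric vector of length 14.
#' @export
emg_features <- function(x, fs, p2p_frame_s = 0.5) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty EMG window")
  d1 <- abs(diff(x))
  d2 <- abs(diff(x, differences = 2L))
  s <- stats::sd(x)
  z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  frame <- max(1L, round(p2p_frame_s * fs))
  starts <- seq.int(1L, length(x), by = frame)
  p2p <- vapply(starts, function(s0) {
    seg <- x[s0:min(length(x), s0 + frame - 1L)]
    max(seg) - min(seg)
  }, numeric(1))
  imin <- local_minima(x)
  imax <- local_maxima(x)
  out <- c(
    peak = max(abs(x)),
    p2p_mean = mean(p2p),
    rms = sqrt(mean(x^2)),
    masd2 = if (length(d2)) mean(d2) else 0,
    masd1 = if (length(d1)) mean(d1) else 0,
    masd2_norm = if (length(z) > 2L) mean(abs(diff(z, differences = 2L))) else 0,
    masd1_norm = if (length(z) > 1L) mean(abs(diff(z))) else 0,
    local_min_mean = if (length(imin)) mean(x[imin]) else x[1L],
    local_max_mean = if (length(imax)) mean(x[imax]) else x[1L],
    mean_abs = mean(abs(x)),
    variance = if (length(x) > 1L) stats::var(x) else 0,
    sd = if (length(x) > 1L) s else 0,
    range = max(x) - min(x),
    iqr = stats::IQR(x)
  )
  stats::setNames(as.numeric(out), emg_feature_names())
}
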