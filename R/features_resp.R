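#' Empirical mode decomposition by sifting
#'
#' Classic EMD: each intrinsic mode function (IMF) is obtained by repeatedly
#' subtracting the mean of the upper and lower cubic-spline envelopes
#' (through local maxima/minima, endpoint-anchored) until the Cauchy
#' stopping criterion falls below `sd_stop`; the IMF is removed and sifting
#' restarts on the residual until it has fewer than 3 extrema.
#'
#' @param x Numeric vector.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param max_sift Maximum sifting iterations per IMF.
#' @param sd_stop Cauchy criterion threshold (default 0.2).
#' @return List with `imfs` (matrix, one column per IMF; may have zero
#'   columns) and `residual`.
#' @export
emd <- function(x, max_imfs = 10L, max_sift = 50L, sd_stop = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  imfs <- list()
  res <- x
  for (k in seq_len(max_imfs)) {
    if (length(local_maxima(res)) + length(local_minima(res)) < 3L) break
    h <- res
    for (s in seq_len(max_sift)) {
      up <- envelope_spline(h, local_maxima(h))
      lo <- envelope_spline(h, local_minima(h))
      if (is.null(up) || is.null(lo)) break
      m <- (up + lo) / 2
      h_new <- h - m
      crit <- sum((h_new - h)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (crit < sd_stop) break
    }
    imfs[[k]] <- h
    res <- res - h
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs) else
         matrix(numeric(0), nrow = n, ncol = 0),
       residual = res)
}

# Cubic spline envelope through the given extremum indices, anchored at the
# first and last sample to tame edge behaviour. NULL if fewer than 2 knots.
envelope_spline <- function(x, idx) {
  n <- length(x)
  knots <- unique(c(1L, idx, n))
  if (length(knots) < 2L) return(NULL)
  stats::spline(knots, x[knots], xout = seq_len(n), method = "fmm")$y
}

#' Dominant frequency of a signal by zero-padded FFT
#'
#' @param x Numeric vector (mean is removed).
#' @param fs Sampling rate in Hz.
#' @param pad Zero-padding factor for finer frequency resolution.
#' @return Frequency in Hz of the largest non-DC spectral magnitude.
#' @export
dominant_frequency <- function(x, fs, pad = 8L) {
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(length(x) * pad))
  sp <- Mod(stats::fft(c(x, rep(0, nfft - length(x)))))[1:(nfft %/% 2)]
  freqs <- (seq_len(nfft %/% 2) - 1L) * fs / nfft
  freqs[which.max(sp)]
}

#' Derive a respiration signal from a preprocessed PPG
#'
#' Respiration reaches the wrist PPG mostly as amplitude modulation of the
#' cardiac pulse (the band-pass used in preprocessing removes additive
#' baseline drift). The beat-amplitude envelope is therefore formed first —
#' a spline through the systolic peaks — and empirical mode decomposition is
#' applied to that envelope. The respiratory signal is the sum of the IMFs
#' whose dominant frequency lies in `band` (default 0.1-0.5 Hz, i.e. 6-30
#' breaths/min). If no IMF falls in the band, or the candidate carries a
#' negligible fraction of the PPG's amplitude, there is no respiratory
#' component and an error is raised.
#'
#' @param ppg A preprocessed PPG [pp_signal()] of at least 30 s.
#' @param band Respiratory frequency band in Hz.
#' @param min_rel_amp Minimum ratio of respiratory-component SD to PPG SD
#'   below which the component is considered absent.
#' @return A [pp_signal()] named `"rr"` at the PPG sampling rate.
#' @export
derive_respiration <- function(ppg, band = c(0.1, 0.5), min_rel_amp = 0.02) {
  stopifnot(inherits(ppg, "pp_signal"))
  if (signal_duration(ppg) < 30) {
    stop("respiration derivation needs at least 30 s of PPG")
  }
  x <- ppg$samples
  fs <- ppg$fs
  beats <- find_peaks(x, min_prominence = 0.1 * stats::sd(x),
                      min_spacing = round(0.3 * fs))
  if (length(beats) < 4L) stop("no respiratory component: too few PPG beats")
  env <- envelope_spline(x, beats)
  dec <- emd(env - mean(env))
  if (!ncol(dec$imfs)) stop("no respiratory component")
  doms <- apply(dec$imfs, 2L, dominant_frequency, fs = fs)
  sel <- which(doms >= band[1] & doms <= band[2])
  if (!length(sel)) stop("no respiratory component")
  resp <- rowSums(dec$imfs[, sel, drop = FALSE])
  if (stats::sd(resp) < min_rel_amp * stats::sd(x)) {
    stop("no respiratory component")
  }
  pp_signal(resp, fs, ppg$t0, "rr")
}

#' Names of the respiration features, in column order
#' @return Character vector of 10 names.
#' @export
rr_feature_names <- function() {
  c("n_inhale_peaks", "mean", "max", "min", "max_minus_min", "sd",
    "peak_interval_mean", "peak_interval_sd", "peak_interval_rmssd",
    "inhale_duration_sd")
}

#' Features of one respiration window
#'
#' Inhale peaks are local maxima with topographic prominence of at least
#' `prominence_frac` of the window's range, spaced at least `min_spacing_s`
#' apart. Inhale duration is the time from the preceding trough to the
#' peak. With fewer than 2 peaks the interval features are the `NA`
#' missing-value sentinel.
#'
#' @param x Numeric vector: one window of the respiration signal.
#' @param fs Sampling rate in Hz.
#' @param prominence_frac Prominence threshold as a fraction of the range.
#' @param min_spacing_s Minimum spacing between inhale peaks in seconds.
#' @return Named numeric vector of length 10.
#' @export
rr_features <- function(x, fs, prominence_frac = 0.2, min_spacing_s = 1.5) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty respiration window")
  rng <- max(x) - min(x)
  pk <- find_peaks(x, min_prominence = prominence_frac * rng,
                   min_spacing = round(min_spacing_s * fs))
  base <- c(
    n_inhale_peaks = length(pk),
    mean = mean(x), max = max(x), min = min(x), max_minus_min = rng,
    sd = if (length(x) > 1L) stats::sd(x) else 0
  )
  if (length(pk) >= 2L) {
    iv <- diff(pk) / fs
    ivd <- diff(iv)
    intervals <- c(
      peak_interval_mean = mean(iv),
      peak_interval_sd = if (length(iv) > 1L) stats::sd(iv) else 0,
      peak_interval_rmssd = if (length(ivd)) sqrt(mean(ivd^2)) else 0
    )
  } else {
    intervals <- c(peak_interval_mean = NA_real_, peak_interval_sd = NA_real_,
                   peak_interval_rmssd = NA_real_)
  }
  troughs <- local_minima(x)
  durs <- vapply(pk, function(p) {
    prev <- troughs[troughs < p]
    if (length(prev)) (p - max(prev)) / fs else NA_real_
  }, numeric(1))
  durs <- durs[is.finite(durs)]
  dur_sd <- if (length(durs) >= 2L) stats::sd(durs)
            else if (length(pk) >= 2L) 0 else NA_real_
  out <- c(base, intervals, inhale_duration_sd = dur_sd)
  stats::setNames(as.numeric(out), rr_feature_names())
}
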