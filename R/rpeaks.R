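#' Detect R-peaks in a preprocessed ECG
#'
#' Deterministic Pan-Tompkins-style QRS detector: band-pass to the QRS band
#' (5-15 Hz), differentiate, square, integrate over a 150 ms moving window,
#' threshold adaptively, and enforce a 200 ms refractory period. Each
#' detection is then refined to the local maximum of the input ECG within
#' +/- 75 ms so peak times line up with the R wave itself. The detector sits
#' behind a plain function interface so a learned detector could be swapped
#' in.
#'
#' @param ecg A preprocessed ECG [pp_signal()].
#' @param threshold_frac Fraction of the smoothed running amplitude used as
#'   the detection threshold (default 0.35).
#' @return An object of class `pp_nn`: list with `r_peak_times` (seconds)
#'   and `nn_ms` (successive R-R intervals, milliseconds). Fewer than two
#'   peaks raise an error.
#' @export
detect_r_peaks <- function(ecg, threshold_frac = 0.35) {
  stopifnot(inherits(ecg, "pp_signal"))
  fs <- ecg$fs
  x <- ecg$samples
  qrs_hi <- min(15, 0.45 * fs)
  bp <- if (fs > 12) {
    filtfilt_butter(filtfilt_butter(x, 2, 5 / (fs / 2), "high"),
                    2, qrs_hi / (fs / 2), "low")
  } else x
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  integ <- moving_average(pp_signal(sq, fs), 0.150)$samples
  # adaptive threshold: fraction of a slow running envelope of the
  # integrated energy (2 s rolling max, smoothed)
  env <- running_max(integ, max(1L, round(2 * fs)))
  env <- moving_average(pp_signal(env, fs), 1)$samples
  thr <- threshold_frac * env
  refr <- round(0.2 * fs)
  cand <- find_peaks(integ, min_prominence = 0, min_spacing = refr)
  cand <- cand[integ[cand] > thr[cand] & integ[cand] > 1e-12]
  if (length(cand) < 2L) stop("fewer than 2 R-peaks detected")
  # refine to the R wave apex on the input ECG
  half <- round(0.075 * fs)
  half <- as.integer(half)
  peaks <- vapply(as.integer(cand), function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; re-apply the refractory constraint
  keep <- c(TRUE, diff(peaks) >= refr)
  peaks <- peaks[keep]
  if (length(peaks) < 2L) stop("fewer than 2 R-peaks detected")
  r_times <- ecg$t0 + (peaks - 1L) / fs
  nn_series(r_times)
}

# Centered sliding maximum via the prefix/suffix block-max trick, O(n).
running_max <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  w2 <- 2L * half + 1L
  z <- c(rep(-Inf, half), x, rep(-Inf, half))
  m <- ceiling(length(z) / w2) * w2
  z <- c(z, rep(-Inf, m - length(z)))
  blk <- matrix(z, nrow = w2)
  pre <- as.numeric(apply(blk, 2, cummax))
  suf <- as.numeric(apply(blk[w2:1, , drop = FALSE], 2, cummax)[w2:1, , drop = FALSE])
  i <- seq_len(n)           # window [i, i + w2 - 1] in z == centered at x[i]
  pmax(suf[i], pre[i + w2 - 1L])
}

#' Construct an NN-interval series from R-peak times
#'
#' @param r_peak_times Strictly increasing R-peak times in seconds.
#' @return `pp_nn` object with `r_peak_times` and `nn_ms` (all positive).
#' @export
nn_series <- function(r_peak_times) {
  if (length(r_peak_times) >= 2L && any(diff(r_peak_times) <= 0)) {
    stop("R-peak times must be strictly increasing")
  }
  structure(
    list(r_peak_times = as.numeric(r_peak_times),
         nn_ms = diff(as.numeric(r_peak_times)) * 1000),
    class = "pp_nn"
  )
}

#' @export
print.pp_nn <- function(x, ...) {
  cat(sprintf("<pp_nn: %d peaks, %d NN intervals, mean %.1f ms>\n",
              length(x$r_peak_times), length(x$nn_ms),
              if (length(x$nn_ms)) mean(x$nn_ms) else NA_real_))
  invisible(x)
}
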