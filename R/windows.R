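#' Slice a signal into fixed-length analysis windows
#'
#' Windows have exactly `round(window_len * fs)` samples. The default step
#' equals the window length, i.e. non-overlapping windows.
#'
#' @param sig A [pp_signal()].
#' @param window_len Window length in seconds (5.5 or 10 in the pipeline).
#' @param step_s Hop between window starts in seconds; default `window_len`.
#' @return List of windows, each a list with `t_start`, `t_end`, `idx`
#'   (sample index range) and `samples`. Empty list (with a warning) if the
#'   signal is shorter than one window.
#' @export
sliding_windows <- function(sig, window_len, step_s = NULL) {
  stopifnot(inherits(sig, "pp_signal"))
  if (is.null(step_s)) step_s <- window_len
  n <- length(sig$samples)
  wlen <- round(window_len * sig$fs)
  if (wlen > n) {
    warning("signal shorter than one window; returning no windows")
    return(list())
  }
  step <- max(1L, round(step_s * sig$fs))
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  lapply(starts, function(s0) {
    idx <- s0:(s0 + wlen - 1L)
    list(t_start = sig$t0 + (s0 - 1L) / sig$fs,
         t_end = sig$t0 + (s0 - 1L + wlen) / sig$fs,
         idx = idx,
         samples = sig$samples[idx])
  })
}

# Local extrema by strict neighbour comparison; plateaus take the first
# sample of the run. Returns indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_max <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_max]
}

local_minima <- function(x) local_maxima(-x)

# Peak finder with topographic prominence and a minimum peak spacing.
# Candidates are strict local maxima; prominence is height above the higher
# of the two minima separating the peak from nearer higher ground. Peaks are
# accepted greedily by height under the spacing constraint.
find_peaks <- function(x, min_prominence = 0, min_spacing = 0) {
  cand <- local_maxima(x)
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    right <- x[seq.int(i + 1L, length(x))]
    higher_l <- which(left >= h)
    base_l <- if (length(higher_l)) min(x[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    higher_r <- which(right >= h)
    base_r <- if (length(higher_r)) {
      min(x[(i + 1L):(i + min(higher_r) - 1L)])
    } else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep) || min_spacing <= 0) return(sort(keep))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc) || all(abs(acc - i) >= min_spacing)) acc <- c(acc, i)
  }
  sort(acc)
}
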