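#' Decompose a preprocessed EDA signal into tonic, phasic and residual
#'
#' Convex-optimization decomposition in the style of cvxEDA: the phasic
#' component is a sparse nonnegative sudomotor driver convolved with a
#' two-time-constant (Bateman) impulse response, the tonic component is a
#' smooth cubic B-spline plus linear drift, and the residual is what
#' remains. The fit solves
#' \deqn{\min_{u \ge 0,\, c}\ \tfrac12\|y - K u - B c\|^2 + \lambda \textstyle\sum_i u_i}
#' by FISTA with a nonnegative soft-threshold proximal step, re-projecting
#' the tonic coefficients at every iteration. Because the impulse response
#' is nonnegative and the driver is constrained nonnegative, the phasic
#' component is nonnegative elementwise, and tonic + phasic + residual
#' reconstructs the input exactly.
#'
#' @param eda A preprocessed EDA [pp_signal()] of at least 10 s.
#' @param tau0 Rise time constant of the SCR impulse response, seconds.
#' @param tau1 Decay time constant, seconds.
#' @param lambda Sparsity weight on the driver (microsiemens scale).
#' @param knot_spacing_s Tonic spline knot spacing in seconds.
#' @param max_iter FISTA iteration budget.
#' @return Object of class `pp_eda_decomp`: list with `tonic`, `phasic`,
#'   `residual` (same length as input), `driver`, and `fs`.
#' @export
eda_decompose <- function(eda, tau0 = 0.7, tau1 = 2.0, lambda = 0.05,
                          knot_spacing_s = 10, max_iter = 300L) {
  stopifnot(inherits(eda, "pp_signal"))
  y <- eda$samples
  n <- length(y)
  fs <- eda$fs
  if (n / fs < 10) stop("EDA decomposition needs at least 10 s of signal")
  h <- scr_irf(fs, tau0, tau1)
  tt <- seq_len(n) / fs
  B <- tonic_basis(tt, knot_spacing_s)
  qrB <- qr(B)
  Kfun <- function(u) conv_causal(u, h, n)
  Ktfun <- function(v) corr_causal(v, h, n)
  L <- sum(h)^2  # upper bound on the squared operator norm of K
  u <- numeric(n); z <- u; tk <- 1
  cvec <- qr.coef(qrB, y)
  for (it in seq_len(max_iter)) {
    r <- y - Kfun(z)
    cvec <- qr.coef(qrB, r)
    grad <- -Ktfun(r - drop(B %*% cvec))
    u_new <- pmax(0, z - (grad + lambda) / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- u_new + ((tk - 1) / t_new) * (u_new - u)
    if (max(abs(u_new - u)) < 1e-10 && it > 10L) { u <- u_new; break }
    u <- u_new; tk <- t_new
  }
  phasic <- Kfun(u)
  cvec <- qr.coef(qrB, y - phasic)
  tonic <- drop(B %*% cvec)
  structure(
    list(tonic = tonic, phasic = phasic, residual = y - tonic - phasic,
         driver = u, fs = fs),
    class = "pp_eda_decomp"
  )
}

# Bateman-shaped SCR impulse response, peak-normalized, truncated where it
# decays below 1e-4 of its peak.
scr_irf <- function(fs, tau0, tau1) {
  t <- seq(0, 12 * max(tau0, tau1), by = 1 / fs)
  h <- exp(-t / tau1) - exp(-t / tau0)
  h <- h / max(h)
  h[seq_len(max(which(h > 1e-4)))]
}

# Causal convolution (K u)[i] = sum_j h[i-j+1] u[j], first n samples.
conv_causal <- function(u, h, n) {
  full <- stats::convolve(u, rev(h), type = "open")
  full[seq_len(n)]
}

# Adjoint (K^T v)[j] = sum_i h[i-j+1] v[i].
corr_causal <- function(v, h, n) {
  m <- length(h)
  full <- stats::convolve(v, h, type = "open")
  full[m:(m + n - 1L)]
}

# Cubic B-spline basis with evenly spaced interior knots; spans constants
# and linear drift by construction.
tonic_basis <- function(tt, knot_spacing_s) {
  dur <- max(tt) - min(tt)
  nk <- max(0L, floor(dur / knot_spacing_s) - 1L)
  knots <- if (nk > 0L) {
    seq(min(tt), max(tt), length.out = nk + 2L)[-c(1L, nk + 2L)]
  } else NULL
  unclass(splines::bs(tt, knots = knots, degree = 3L, intercept = TRUE))
}

#' Count phasic peaks (skin conductance responses)
#'
#' Peaks of the phasic component with topographic prominence of at least
#' `prominence` microsiemens and at least `min_spacing_s` apart.
#'
#' @param phasic Numeric vector (phasic EDA component).
#' @param fs Sampling rate in Hz.
#' @param prominence Minimum prominence in microsiemens (default 0.01).
#' @param min_spacing_s Minimum spacing between counted SCRs in seconds.
#' @return Integer vector of peak indices.
#' @export
scr_peaks <- function(phasic, fs, prominence = 0.01, min_spacing_s = 1) {
  find_peaks(phasic, min_prominence = prominence,
             min_spacing = round(min_spacing_s * fs))
}

#' Names of the EDA features, in column order
#' @return Character vector of 12 names.
#' @export
eda_feature_names <- function() {
  c("n_phasic_peaks", "mean", "max", "min", "max_minus_min", "sd", "iqr",
    "rms", "local_min_mean", "local_max_mean", "mad1", "mad2")
}

#' Statistical features of one EDA window
#'
#' The SCR count comes from the phasic component; the remaining statistics
#' are computed on the clean (preprocessed) signal: mean, max, min, range,
#' SD, IQR, RMS, means of local minima/maxima, and mean absolute first and
#' second differences.
#'
#' @param clean Numeric vector: window of the preprocessed EDA signal.
#' @param phasic Numeric vector: matching window of the phasic component.
#' @param fs Sampling rate in Hz.
#' @param prominence SCR prominence threshold in microsiemens.
#' @return Named numeric vector of length 12.
#' @export
eda_features <- function(clean, phasic, fs, prominence = 0.01) {
  x <- as.numeric(clean)
  if (!length(x)) stop("empty EDA window")
  imin <- local_minima(x)
  imax <- local_maxima(x)
  out <- c(
    n_phasic_peaks = length(scr_peaks(phasic, fs, prominence)),
    mean = mean(x), max = max(x), min = min(x),
    max_minus_min = max(x) - min(x),
    sd = if (length(x) > 1L) stats::sd(x) else 0,
    iqr = stats::IQR(x),
    rms = sqrt(mean(x^2)),
    local_min_mean = if (length(imin)) mean(x[imin]) else x[1L],
    local_max_mean = if (length(imax)) mean(x[imax]) else x[1L],
    mad1 = if (length(x) > 1L) mean(abs(diff(x))) else 0,
    mad2 = if (length(x) > 2L) mean(abs(diff(x, differences = 2L))) else 0
  )
  stats::setNames(as.numeric(out), eda_feature_names())
}
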