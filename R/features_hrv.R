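#' Names of the time-domain HRV features, in column order
#' @return Character vector of 19 names.
#' @export
hrv_feature_names <- function() {
  c("nn_slope", "nn_count", "nn_mean", "nn_min", "nn_max", "nn_sd",
    "diff_mean", "diff_min", "diff_max", "sdsd", "rmssd",
    "nn20_count", "nn50_count", "pnn20", "pnn50",
    "hr_mean", "hr_min", "hr_max", "hr_sd")
}

#' Time-domain HRV features from an NN-interval series
#'
#' Computes the 19 time-domain heart-rate-variability features used by the
#' pipeline: the least-squares slope of NN intervals against interval index;
#' 5 NN statistics (count, mean, min, max, SD); 9 successive-difference
#' features (mean, min, max of the signed differences, SDSD, RMSSD, counts
#' and percentages of |differences| above 20 ms and 50 ms); and 4 heart-rate
#' statistics, with per-interval HR = 60000 / NN(ms).
#'
#' @param nn A `pp_nn` from [detect_r_peaks()] or [nn_series()], or a plain
#'   numeric vector of NN intervals in milliseconds.
#' @param min_intervals Minimum number of NN intervals required (default 3);
#'   shorter series return the all-`NA` missing-value sentinel. The formulas
#'   themselves are defined down to 2 intervals.
#' @return Named numeric vector of length 19, or all-`NA` sentinel (same
#'   names) when fewer than `min_intervals` intervals are available.
#' @export
hrv_time_features <- function(nn, min_intervals = 3L) {
  x <- if (inherits(nn, "pp_nn")) nn$nn_ms else as.numeric(nn)
  nm <- hrv_feature_names()
  if (length(x) < max(2L, min_intervals)) {
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  d <- diff(x)
  hr <- 60000 / x
  out <- c(
    nn_slope = unname(stats::coef(stats::lm.fit(
      cbind(1, seq_along(x)), x))[2L]),
    nn_count = length(x),
    nn_mean = mean(x), nn_min = min(x), nn_max = max(x), nn_sd = stats::sd(x),
    diff_mean = mean(d), diff_min = min(d), diff_max = max(d),
    sdsd = stats::sd(d), rmssd = sqrt(mean(d^2)),
    nn20_count = sum(abs(d) > 20), nn50_count = sum(abs(d) > 50),
    pnn20 = 100 * sum(abs(d) > 20) / length(d),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    hr_mean = mean(hr), hr_min = min(hr), hr_max = max(hr), hr_sd = stats::sd(hr)
  )
  stats::setNames(as.numeric(out), nm)
}
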