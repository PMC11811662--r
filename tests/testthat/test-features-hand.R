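test_that("sliding windows have exact sample counts and window arithmetic", {
  s <- pp_signal(rnorm(60 * 100), 100)
  w10 <- sliding_windows(s, 10)
  expect_length(w10, 6)
  expect_true(all(vapply(w10, function(w) length(w$samples), numeric(1)) ==
                    1000))
  w55 <- sliding_windows(s, 5.5)
  expect_length(w55, 10)  # floor(60 / 5.5)
  expect_warning(out <- sliding_windows(pp_signal(rnorm(500), 100), 10),
                 "shorter")
  expect_length(out, 0)
})

test_that("R-peak detector recovers a metronome rhythm", {
  m <- make_metronome_ecg(30)
  nn <- detect_r_peaks(butterworth_filter(m$sig, "bandpass", c(0.1, 225)))
  expect_true(abs(length(nn$r_peak_times) - 30) <= 1)
  expect_true(all(abs(nn$nn_ms - 1000) < 5))
  expect_error(detect_r_peaks(pp_signal(rep(0, 5000), 500)), "R-peaks")
  # one deleted beat leaves a single ~2000 ms gap
  md <- make_metronome_ecg(30, drop_beat = 15)
  nnd <- detect_r_peaks(butterworth_filter(md$sig, "bandpass", c(0.1, 225)))
  expect_equal(sum(abs(nnd$nn_ms - 2000) < 50), 1)
})

test_that("HRV features match hand-computed examples", {
  f <- hrv_time_features(rep(800, 10))
  expect_equal(f[["nn_mean"]], 800)
  expect_equal(f[["nn_sd"]], 0)
  expect_equal(f[["rmssd"]], 0)
  expect_equal(f[["sdsd"]], 0)
  expect_equal(f[["pnn20"]], 0)
  expect_equal(f[["hr_mean"]], 75)
  expect_equal(f[["nn_slope"]], 0)
  expect_equal(f[["nn_count"]], 10)

  f2 <- hrv_time_features(c(800, 810, 790, 805))
  expect_equal(f2[["rmssd"]], sqrt((100 + 400 + 225) / 3), tolerance = 1e-9)
  expect_equal(f2[["nn20_count"]], 0)
  expect_equal(f2[["nn_count"]], 4)
  expect_equal(f2[["diff_min"]], -20)
  expect_equal(f2[["diff_max"]], 15)

  f3 <- hrv_time_features(c(700, 760), min_intervals = 2)
  expect_equal(f3[["nn50_count"]], 1)
  expect_equal(f3[["pnn50"]], 100)
  # under the contract's default, short series yield the missing sentinel
  expect_true(all(is.na(hrv_time_features(c(700, 760)))))
  expect_length(hrv_feature_names(), 19)
})

test_that("HRV features equal a brute-force oracle on random series", {
  # independent transcription of the formulas, loop-based on purpose
  oracle <- function(x) {
    n <- length(x)
    d <- numeric(n - 1)
    for (i in seq_len(n - 1)) d[i] <- x[i + 1] - x[i]
    hr <- 60000 / x
    idx <- seq_len(n)
    slope <- sum((idx - mean(idx)) * (x - mean(x))) /
      sum((idx - mean(idx))^2)
    c(slope, n, mean(x), min(x), max(x), sd(x),
      mean(d), min(d), max(d), sd(d), sqrt(sum(d^2) / length(d)),
      sum(abs(d) > 20), sum(abs(d) > 50),
      100 * sum(abs(d) > 20) / length(d), 100 * sum(abs(d) > 50) / length(d),
      mean(hr), min(hr), max(hr), sd(hr))
  }
  set.seed(11)
  for (i in seq_len(1000)) {
    x <- stats::runif(sample(3:40, 1), 400, 1400)
    expect_equal(unname(hrv_time_features(x)), oracle(x), tolerance = 1e-9)
  }
})

test_that("EMG features match hand computations and scale correctly", {
  f <- emg_features(rep(2, 100), fs = 100)
  expect_equal(f[["peak"]], 2)
  expect_equal(f[["rms"]], 2)
  expect_equal(f[["mean_abs"]], 2)
  expect_equal(f[["masd1"]], 0)
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["range"]], 0)
  expect_equal(f[["iqr"]], 0)
  expect_equal(f[["local_min_mean"]], 2)  # constant fallback

  x <- rep(c(0, 1, 0, -1), 25)
  f2 <- emg_features(x, fs = 100)
  expect_equal(f2[["rms"]], sqrt(0.5), tolerance = 1e-9)
  expect_equal(f2[["range"]], 2)
  expect_equal(f2[["mean_abs"]], 0.5)
  expect_length(f2, 14)

  # scale equivariance: |c| on amplitude features, invariance of normalized
  set.seed(2)
  w <- rnorm(500)
  a <- emg_features(w, 500); b <- emg_features(-3 * w, 500)
  for (nm in c("peak", "rms", "sd", "range", "iqr", "mean_abs")) {
    expect_equal(b[[nm]], 3 * a[[nm]], tolerance = 1e-8)
  }
  expect_equal(b[["variance"]], 9 * a[["variance"]], tolerance = 1e-8)
  expect_equal(b[["masd1_norm"]], a[["masd1_norm"]], tolerance = 1e-8)
  expect_equal(b[["masd2_norm"]], a[["masd2_norm"]], tolerance = 1e-8)
})

test_that("EDA decomposition separates tonic trends from injected SCRs", {
  # pure slow ramp: essentially no phasic energy
  ramp <- make_eda(120, scr_times = numeric(0), ramp = 0.01)
  dec <- eda_decompose(ramp)
  expect_lt(sum(dec$phasic^2), 0.05 * sum((ramp$samples - mean(ramp$samples))^2))
  expect_lt(max(abs(dec$tonic + dec$phasic + dec$residual - ramp$samples)),
            1e-6)
  expect_true(all(dec$phasic > -1e-9))
  # ramp + 3 well-separated SCRs: exactly 3 phasic peaks
  e3 <- make_eda(120, scr_times = c(20, 55, 90))
  dec3 <- eda_decompose(e3)
  expect_equal(length(scr_peaks(dec3$phasic, 4, prominence = 0.01)), 3)
  # zero signal stays zero
  z <- eda_decompose(pp_signal(rep(0, 400), 4))
  expect_lt(max(abs(z$phasic)), 1e-8)
  expect_lt(max(abs(z$tonic)), 1e-6)
  expect_error(eda_decompose(pp_signal(rep(1, 8), 4)), "10 s")
})

test_that("EDA features have the fixed cardinality and correct peak counts", {
  f <- eda_features(rep(1, 40), rep(0, 40), fs = 4)
  expect_equal(f[["n_phasic_peaks"]], 0)
  expect_equal(f[["mean"]], 1)
  expect_equal(f[["max"]], 1)
  expect_equal(f[["rms"]], 1)
  expect_equal(f[["max_minus_min"]], 0)
  expect_equal(f[["sd"]], 0)
  expect_length(f, 12)
  e2 <- make_eda(40, scr_times = c(8, 25))
  dec <- eda_decompose(e2)
  f2 <- eda_features(e2$samples, dec$phasic, fs = 4)
  expect_equal(f2[["n_phasic_peaks"]], 2)
})

test_that("respiration is recovered from PPG amplitude modulation", {
  fs <- 64
  tt <- (seq_len(120 * fs) - 1) / fs
  am <- pp_signal((1 + 0.3 * sin(2 * pi * 0.25 * tt)) *
                    sin(2 * pi * 1.2 * tt), fs)
  resp <- derive_respiration(am)
  expect_equal(dominant_frequency(resp$samples, fs), 0.25, tolerance = 0.02)
  # a faster modulation is tracked too
  am45 <- pp_signal((1 + 0.3 * sin(2 * pi * 0.45 * tt)) *
                      sin(2 * pi * 1.2 * tt), fs)
  expect_equal(dominant_frequency(derive_respiration(am45)$samples, fs),
               0.45, tolerance = 0.02)
  # an unmodulated carrier has no respiratory component
  pure <- pp_signal(sin(2 * pi * 1.2 * tt), fs)
  expect_error(derive_respiration(pure), "no respiratory component")
  expect_error(derive_respiration(pp_signal(rnorm(64), 64)), "30 s")
})

test_that("respiration features count inhale peaks analytically", {
  fs <- 8
  tt <- (seq_len(60 * fs) - 1) / fs
  x <- sin(2 * pi * 0.25 * tt)
  f <- rr_features(x, fs)
  expect_equal(f[["n_inhale_peaks"]], 15)
  expect_equal(f[["peak_interval_mean"]], 4, tolerance = 0.01)
  expect_lt(f[["peak_interval_sd"]], 0.01)
  expect_length(f, 10)
  # 10 s window: 2 or 3 peaks depending on phase, interval still 4 s
  f10 <- rr_features(x[seq_len(10 * fs)], fs)
  expect_true(f10[["n_inhale_peaks"]] %in% c(2, 3))
  expect_equal(f10[["peak_interval_mean"]], 4, tolerance = 0.01)
  # < 2 peaks: interval features are the missing sentinel
  f1 <- rr_features(x[seq_len(4 * fs)], fs)
  expect_true(is.na(f1[["peak_interval_mean"]]))
})

test_that("handcrafted extraction yields the fixed per-modality counts", {
  rec <- fixture_preprocessed()
  feats <- suppressMessages(extract_handcrafted(rec, window_len = 10))
  expect_setequal(names(feats), c("ecg", "emg", "eda", "rr"))
  expect_equal(ncol(feature_matrix(feats$ecg)), 19)
  expect_equal(ncol(feature_matrix(feats$emg)), 70)
  expect_equal(ncol(feature_matrix(feats$eda)), 12)
  expect_equal(ncol(feature_matrix(feats$rr)), 10)
  # 300 s of signal, 10 s windows: at most 30 per modality, minus drops
  expect_lte(nrow(feats$ecg), 30)
  expect_gt(nrow(feats$ecg), 20)
  # feature matrices are column-stable and reproducible
  feats2 <- suppressMessages(extract_handcrafted(rec, window_len = 10))
  expect_identical(feats, feats2)
})
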