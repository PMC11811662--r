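fft_amp_at <- function(x, fs, f0) {
  n <- length(x)
  sp <- Mod(stats::fft(x)) / n * 2
  freqs <- (seq_len(n) - 1) * fs / n
  sp[which.min(abs(freqs - f0))]
}

test_that("Butterworth band-pass rejects DC and passes in-band tones", {
  fs <- 500
  n <- 120 * fs
  tt <- (seq_len(n) - 1) / fs
  ctr <- (n / 4):(3 * n / 4)

  flat <- butterworth_filter(pp_signal(rep(1, n), fs), "bandpass", c(0.1, 40))
  expect_lt(max(abs(flat$samples[ctr])), 1e-3)

  s5 <- butterworth_filter(pp_signal(sin(2 * pi * 5 * tt), fs),
                           "bandpass", c(0.5, 40), order = 4)
  expect_equal(max(abs(s5$samples[ctr])), 1, tolerance = 0.02)
  expect_length(s5$samples, n)

  slow <- butterworth_filter(pp_signal(sin(2 * pi * 0.01 * tt), fs),
                             "highpass", 20)
  expect_lt(max(abs(slow$samples[ctr])), 0.01)

  expect_error(butterworth_filter(pp_signal(rnorm(100), 100),
                                  "lowpass", 60), "Nyquist")
})

test_that("notch filter removes the target tone and spares neighbours", {
  fs <- 500
  tt <- (seq_len(20 * fs) - 1) / fs
  ctr <- (5 * fs):(15 * fs)
  y50 <- notch_filter(pp_signal(sin(2 * pi * 50 * tt), fs), 50, 30)
  expect_lt(max(abs(y50$samples[ctr])), 0.1)
  y30 <- notch_filter(pp_signal(sin(2 * pi * 30 * tt), fs), 50, 30)
  expect_equal(max(abs(y30$samples[ctr])), 1, tolerance = 0.02)
  z <- notch_filter(pp_signal(rep(0, 1000), fs), 50, 30)
  expect_equal(z$samples, rep(0, 1000))
  expect_error(notch_filter(pp_signal(rnorm(100), 100), 60), "Nyquist")
})

test_that("moving average is exact on hand-computable inputs", {
  expect_equal(moving_average(pp_signal(rep(3.5, 40), 4), 1)$samples,
               rep(3.5, 40))
  alt <- moving_average(pp_signal(rep(c(1, -1), 20), 4), 1)
  expect_equal(alt$samples[3:37], rep(0, 35))
  imp <- numeric(20); imp[10] <- 4
  sm <- moving_average(pp_signal(imp, 4), 1)$samples
  expect_equal(sum(sm > 0.999), 4)  # plateau of height 1 over 4 samples
  expect_equal(max(sm), 1)
  expect_error(moving_average(pp_signal(1:3, 4), 10), "longer than signal")
})

test_that("modality pipelines remove their target noise", {
  fs <- 500
  tt <- (seq_len(60 * fs) - 1) / fs
  ctr <- (15 * fs):(45 * fs)
  # ECG: 0.05 Hz baseline wander reduced >= 90%
  ecg <- pp_signal(sin(2 * pi * 1.1 * tt) + sin(2 * pi * 0.05 * tt), fs)
  rec <- pp_recording("s", list(ecg = list(ecg)), schema = NULL)
  out <- preprocess_modality(rec, "ecg")$channels$ecg[[1]]
  expect_lt(fft_amp_at(out$samples[ctr], fs, 0.05) /
              fft_amp_at(ecg$samples[ctr], fs, 0.05), 0.1)
  # EMG: injected 50 Hz tone reduced >= 20 dB
  emg <- pp_signal(rnorm(length(tt), sd = 0.05) + sin(2 * pi * 50 * tt), fs)
  rec <- pp_recording("s", list(emg = list(emg)), schema = NULL)
  out <- preprocess_modality(rec, "emg")$channels$emg[[1]]
  expect_lt(fft_amp_at(out$samples[ctr], fs, 50) /
              fft_amp_at(emg$samples[ctr], fs, 50), 0.1)
  # EDA: smoothing preserves an already-clean slow signal
  tte <- (seq_len(240) - 1) / 4
  eda <- pp_signal(5 + 0.5 * sin(2 * pi * 0.05 * tte), 4)
  rec <- pp_recording("s", list(eda = list(eda)), schema = NULL)
  out <- preprocess_modality(rec, "eda")$channels$eda[[1]]
  expect_gt(stats::cor(out$samples, eda$samples), 0.99)
  expect_error(preprocess_modality(rec, "ppg"), "not present")
})

test_that("filtering is zero-phase and linear", {
  fs <- 4
  tt <- (seq_len(240 * fs) - 1) / fs
  x <- sin(2 * pi * 0.3 * tt)
  rec <- pp_recording("s", list(eda = list(pp_signal(5 + x, fs))),
                      schema = NULL)
  y <- preprocess_modality(rec, "eda")$channels$eda[[1]]$samples
  cc <- stats::ccf(y - mean(y), x, lag.max = 8, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  a <- rnorm(2000); b <- rnorm(2000)
  f <- function(v) butterworth_filter(pp_signal(v, 500), "bandpass",
                                      c(1, 40))$samples
  expect_equal(f(2 * a + 3 * b), 2 * f(a) + 3 * f(b), tolerance = 1e-8)
})
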