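# Shared fixtures, built once per test run.

# A small full-montage subject (all four modalities) with default effects.
fixture_subject <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      spec <- cohort_spec(n_subjects = 1, duration_s = 300,
                          activity_len_s = 50)
      val <<- generate_subject(spec, subject_seed = 7, subject_id = "s01")
    }
    val
  }
})

fixture_preprocessed <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- preprocess_recording(fixture_subject()$recording)
    val
  }
})

# Template-beat ECG at an exact 1 Hz rhythm (no noise), for detector tests.
make_metronome_ecg <- function(duration_s = 30, fs = 500, beat_hz = 1,
                               drop_beat = NULL) {
  tt <- (seq_len(duration_s * fs) - 1) / fs
  beats <- seq(0.5, duration_s - 0.5, by = 1 / beat_hz)
  if (!is.null(drop_beat)) beats <- beats[-drop_beat]
  x <- numeric(length(tt))
  for (tb in beats) {
    for (w in list(c(-0.2, 0.15, 0.025), c(-0.03, -0.12, 0.01),
                   c(0, 1, 0.012), c(0.03, -0.2, 0.012),
                   c(0.25, 0.3, 0.05))) {
      x <- x + w[2] * exp(-((tt - tb - w[1]) / w[3])^2 / 2)
    }
  }
  list(sig = pp_signal(x, fs, 0, "ecg"), beats = beats)
}

# Synthetic EDA: slow ramp plus optional Bateman-shaped SCRs.
make_eda <- function(duration_s = 60, fs = 4, scr_times = numeric(0),
                     scr_amp = 0.5, ramp = 0.01, level = 5) {
  tt <- (seq_len(duration_s * fs) - 1) / fs
  x <- level + ramp * tt
  if (length(scr_times)) {
    irf_t <- seq(0, 20, by = 1 / fs)
    irf <- exp(-irf_t / 2) - exp(-irf_t / 0.7)
    irf <- irf / max(irf)
    for (ts in scr_times) {
      i0 <- round(ts * fs) + 1
      idx <- i0:min(length(x), i0 + length(irf) - 1)
      x[idx] <- x[idx] + scr_amp * irf[seq_along(idx)]
    }
  }
  pp_signal(x, fs, 0, "eda")
}

# A labeled toy feature frame for model-level tests: n subjects, two
# informative features separated by class, the rest noise.
make_toy_instances <- function(n_subjects = 5, per_class = 10, n_noise = 8,
                               sep = 2, classes = c("BL", "PL3"), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (ci in seq_along(classes)) {
      n <- per_class
      X <- cbind(matrix(stats::rnorm(n * 2, mean = sep * (ci - 1)), n, 2),
                 matrix(stats::rnorm(n * n_noise), n, n_noise))
      colnames(X) <- paste0("f", seq_len(ncol(X)))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("s%02d", s), modality = "toy",
        t_start = seq_len(n) * 10, t_end = seq_len(n) * 10 + 10,
        window_len = 10, feature_source = "handcrafted", X,
        label = classes[ci], provenance = "strong", check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
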