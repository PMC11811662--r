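#' Specification of a synthetic multimodal cohort
#'
#' Defines the statistical structure of the generated study: per-subject
#' session layout (rest baseline interleaved with light physical-activity
#' segments during which pain is reported), per-subject physiological
#' baselines, and the pain effect sizes that couple the true NRS level to
#' the signals — heart-rate increase and HRV (SDNN) shrinkage, EMG burst
#' amplitude, skin-conductance-response rate, and respiratory rate. Motion
#' artifacts occur uniformly in time (not preferentially during activity),
#' so at zero effect sizes the activity segments are statistically
#' indistinguishable from rest.
#'
#' @param n_subjects Number of subjects (default 20, the study cohort size).
#' @param duration_s Session length per subject in seconds (default 600).
#' @param n_activity Number of activity segments (default 3; each segment
#'   carries one NRS band: 1-3, 4-6, 7-10 in random order).
#' @param activity_len_s Activity segment length (default 80 s).
#' @param annotation_interval_s Spacing of NRS self-reports inside activity
#'   segments (default 20 s).
#' @param pain_profile Optional explicit NRS value per activity segment;
#'   default `NULL` draws one value from each band.
#' @param effect_hr_bpm Heart-rate increase per NRS point (default 1.5).
#' @param effect_sdnn_shrink Fractional SDNN shrink per NRS point
#'   (default 0.05).
#' @param effect_emg_gain EMG burst amplitude gain per NRS point
#'   (default 0.15); burst amplitude is `10 * gain * NRS` in units of the
#'   baseline EMG noise SD, and an NRS-0 segment has no bursts at all.
#' @param effect_scr_rate Additional SCRs per minute per NRS point
#'   (default 0.4).
#' @param effect_rr_bpm Additional breaths per minute per NRS point
#'   (default 0.5).
#' @param hr_range,rr_range,eda_range Per-subject baseline ranges: resting
#'   heart rate in bpm, respiratory rate in breaths/min, tonic EDA level in
#'   microsiemens.
#' @param sdnn_ms Baseline SDNN of the RR intervals in ms (default 50).
#' @param scr_base_rate Baseline SCR rate per minute (default 2).
#' @param scr_min_spacing_s Refractory spacing between SCR onsets in
#'   seconds (default 5, matching the response's own rise-plus-decay time).
#' @param motion_rate Motion artifacts per minute (default 1).
#' @param motion_amp Artifact amplitude relative to each signal's scale.
#' @param noise Relative white-noise level on all channels (1 = default).
#' @param fs Named sampling rates in Hz (`ecg`, `emg` from the biopotential
#'   device; `eda`, `ppg` at wristband rates).
#' @param modalities Modalities to generate.
#' @return A `pp_cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 20L, duration_s = 600,
                        n_activity = 3L, activity_len_s = 80,
                        annotation_interval_s = 20,
                        pain_profile = NULL,
                        effect_hr_bpm = 1.5, effect_sdnn_shrink = 0.05,
                        effect_emg_gain = 0.15, effect_scr_rate = 0.4,
                        effect_rr_bpm = 0.5,
                        hr_range = c(55, 85), rr_range = c(12, 16),
                        eda_range = c(2, 10), sdnn_ms = 50,
                        scr_base_rate = 2, scr_min_spacing_s = 5,
                        motion_rate = 1,
                        motion_amp = 1, noise = 1,
                        fs = c(ecg = 500, emg = 500, eda = 4, ppg = 64),
                        modalities = c("ecg", "emg", "eda", "ppg")) {
  if (n_activity * activity_len_s + (n_activity + 1) * 30 > duration_s) {
    stop("duration too short for the requested activity segments")
  }
  structure(as.list(environment()), class = "pp_cohort_spec")
}

#' Generate one synthetic subject
#'
#' Builds the session timeline, then synthesizes each modality:
#' \describe{
#'   \item{ECG}{Template beats (P-QRS-T) at times whose RR intervals follow
#'     an AR(1) process around 60000/HR(NRS) ms with NRS-shrunk SDNN, plus
#'     baseline wander, powerline hum and white noise.}
#'   \item{EMG}{Broadband noise per channel, powerline hum, and Hann-shaped
#'     activity bursts whose amplitude scales with NRS.}
#'   \item{EDA}{Slow tonic drift plus Bateman-shaped SCRs arriving as a
#'     Poisson process whose rate increases with NRS.}
#'   \item{PPG}{A cardiac oscillation at the instantaneous heart rate,
#'     amplitude-modulated at the NRS-dependent respiratory frequency.}
#' }
#' NRS annotations are emitted only inside activity segments; rest periods
#' become designated baseline spans.
#'
#' @param spec A [cohort_spec()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier string.
#' @return List with `recording` (a [pp_recording()]) and `truth` (beat
#'   times, SCR times, per-segment NRS/class/respiratory frequency, subject
#'   baselines).
#' @export
generate_subject <- function(spec, subject_seed = 1L, subject_id = "s01") {
  stopifnot(inherits(spec, "pp_cohort_spec"))
  set.seed(subject_seed)
  dur <- spec$duration_s
  # timeline: gaps (rest) interleaved with activity segments
  gap <- (dur - spec$n_activity * spec$activity_len_s) / (spec$n_activity + 1)
  act_start <- gap + (seq_len(spec$n_activity) - 1) *
    (spec$activity_len_s + gap)
  segments <- data.frame(t_start = act_start,
                         t_end = act_start + spec$activity_len_s)
  bands <- list(c(1L, 3L), c(4L, 6L), c(7L, 10L))
  nrs_vals <- if (!is.null(spec$pain_profile)) {
    rep_len(as.integer(spec$pain_profile), spec$n_activity)
  } else {
    bs <- bands[(seq_len(spec$n_activity) - 1L) %% 3L + 1L]
    bs <- bs[sample.int(length(bs))]
    vapply(bs, function(b) sample(seq(b[1L], b[2L]), 1L), integer(1))
  }
  segments$nrs <- nrs_vals
  segments$class <- map_nrs_to_class(segments$nrs)
  baseline_spans <- cbind(t_start = c(0, segments$t_end),
                          t_end = c(segments$t_start, dur))
  baseline_spans <- baseline_spans[
    baseline_spans[, 2] - baseline_spans[, 1] > 1e-9, , drop = FALSE]

  nrs_at <- function(t) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(segments))) {
      inside <- t >= segments$t_start[i] & t < segments$t_end[i]
      out[inside] <- segments$nrs[i]
    }
    out
  }

  hr0 <- stats::runif(1, spec$hr_range[1], spec$hr_range[2])
  rr0 <- stats::runif(1, spec$rr_range[1], spec$rr_range[2])
  eda0 <- stats::runif(1, spec$eda_range[1], spec$eda_range[2])

  # ---- beat times: AR(1) RR intervals around the NRS-driven mean -------
  phi <- 0.6
  beat_times <- numeric(0)
  t_cur <- stats::runif(1, 0, 1)
  dev <- 0
  while (t_cur < dur) {
    beat_times <- c(beat_times, t_cur)
    nrs_here <- nrs_at(t_cur)
    mu <- 60000 / (hr0 + spec$effect_hr_bpm * nrs_here)
    sdnn <- spec$sdnn_ms * max(0.1, 1 - spec$effect_sdnn_shrink * nrs_here)
    dev <- phi * dev + stats::rnorm(1, 0, sdnn * sqrt(1 - phi^2))
    t_cur <- t_cur + max(0.3, (mu + dev) / 1000)
  }

  channels <- list()
  truth_resp <- (rr0 + spec$effect_rr_bpm * segments$nrs) / 60
  motion_times <- sort(stats::runif(
    stats::rpois(1, spec$motion_rate * dur / 60), 0, dur))

  add_motion <- function(x, fs, amp) {
    for (tm in motion_times) {
      i0 <- round(tm * fs) + 1L
      len <- round(stats::runif(1, 0.3, 1) * fs)
      idx <- i0:min(length(x), i0 + len - 1L)
      if (length(idx) < 4L || idx[1L] > length(x)) next
      bump <- amp * sin(pi * seq(0, 1, length.out = length(idx))) *
        stats::rnorm(length(idx), 1, 0.3)
      x[idx] <- x[idx] + bump
    }
    x
  }

  if ("ecg" %in% spec$modalities) {
    fs <- spec$fs[["ecg"]]
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    wave <- function(center, amp, width) {
      idx_lo <- max(1L, floor((center - 4 * width) * fs))
      idx_hi <- min(n, ceiling((center + 4 * width) * fs))
      if (idx_lo >= idx_hi) return(invisible(NULL))
      seg <- idx_lo:idx_hi
      x[seg] <<- x[seg] + amp * exp(-((tt[seg] - center) / width)^2 / 2)
      invisible(NULL)
    }
    for (tb in beat_times) {
      wave(tb - 0.2, 0.15, 0.025)   # P
      wave(tb - 0.03, -0.12, 0.01)  # Q
      wave(tb, 1.0, 0.012)          # R
      wave(tb + 0.03, -0.2, 0.012)  # S
      wave(tb + 0.25, 0.3, 0.05)    # T
    }
    x <- x + 0.25 * sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi)) +
      0.05 * sin(2 * pi * 50 * tt) +
      spec$noise * 0.03 * stats::rnorm(n)
    x <- add_motion(x, fs, 0.4 * spec$motion_amp)
    channels$ecg <- list(pp_signal(x, fs, 0, "ecg"))
  }

  if ("emg" %in% spec$modalities) {
    fs <- spec$fs[["emg"]]
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    sigma0 <- 0.02
    channels$emg <- lapply(seq_len(5L), function(ci) {
      x <- sigma0 * spec$noise * stats::rnorm(n) +
        0.01 * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
      for (i in seq_len(nrow(segments))) {
        # burst amplitude in units of the noise floor: 10 x gain x NRS, so
        # the default 15%/point puts an NRS-10 grimace at 15x baseline SD
        amp <- sigma0 * 10 * spec$effect_emg_gain * segments$nrs[i]
        if (amp <= 0) next
        n_burst <- stats::rpois(1, spec$activity_len_s / 5)
        starts <- stats::runif(n_burst, segments$t_start[i],
                               segments$t_end[i] - 1.5)
        for (b0 in starts) {
          blen <- round(stats::runif(1, 0.5, 2) * fs)
          idx <- (round(b0 * fs) + 1L):min(n, round(b0 * fs) + blen)
          env <- sin(pi * seq(0, 1, length.out = length(idx)))
          x[idx] <- x[idx] + amp * env * stats::rnorm(length(idx))
        }
      }
      x <- add_motion(x, fs, 0.05 * spec$motion_amp)
      pp_signal(x, fs, 0, sprintf("emg%d", ci))
    })
  }

  scr_times <- numeric(0)
  if ("eda" %in% spec$modalities) {
    fs <- spec$fs[["eda"]]
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    rate_at <- (spec$scr_base_rate + spec$effect_scr_rate * nrs_at(tt)) / 60
    # thinning: draw candidate events at the max rate, keep proportionally
    max_rate <- max(rate_at)
    # keep each event's full impulse response inside the record so the
    # injected count is well-defined ground truth
    n_cand <- stats::rpois(1, max_rate * dur)
    cand <- sort(stats::runif(n_cand, 0, dur - 12))
    keep_p <- (spec$scr_base_rate +
                 spec$effect_scr_rate * nrs_at(cand)) / 60 / max_rate
    scr_times <- cand[stats::runif(length(cand)) < keep_p]
    if (length(scr_times) > 1L) {           # sudomotor refractory period
      kept <- scr_times[1L]
      for (ts in scr_times[-1L]) {
        if (ts - kept[length(kept)] >= spec$scr_min_spacing_s) {
          kept <- c(kept, ts)
        }
      }
      scr_times <- kept
    }
    x <- eda0 + 0.3 * sin(2 * pi * tt / 300 + stats::runif(1, 0, 2 * pi)) +
      0.0005 * tt
    irf <- scr_irf(fs, 0.7, 2.0)
    for (ts in scr_times) {
      amp <- stats::runif(1, 0.2, 0.6)
      i0 <- round(ts * fs) + 1L
      idx <- i0:min(n, i0 + length(irf) - 1L)
      x[idx] <- x[idx] + amp * irf[seq_along(idx)]
    }
    x <- x + spec$noise * 0.01 * stats::rnorm(n)
    x <- add_motion(x, fs, 0.05 * spec$motion_amp)
    channels$eda <- list(pp_signal(x, fs, 0, "eda"))
  }

  if ("ppg" %in% spec$modalities) {
    fs <- spec$fs[["ppg"]]
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    f_card <- (hr0 + spec$effect_hr_bpm * nrs_at(tt)) / 60
    f_resp <- (rr0 + spec$effect_rr_bpm * nrs_at(tt)) / 60
    ph_card <- 2 * pi * cumsum(f_card) / fs
    ph_resp <- 2 * pi * cumsum(f_resp) / fs
    x <- (1 + 0.3 * sin(ph_resp)) * sin(ph_card) +
      spec$noise * 0.02 * stats::rnorm(n)
    x <- add_motion(x, fs, 0.3 * spec$motion_amp)
    channels$ppg <- list(pp_signal(x, fs, 0, "ppg"))
  }

  ann_t <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    seq(segments$t_start[i] + spec$annotation_interval_s / 2,
        segments$t_end[i], by = spec$annotation_interval_s)
  }))
  ann <- pp_annotations(ann_t, nrs_at(ann_t))

  schema <- if (setequal(spec$modalities, c("ecg", "emg", "eda", "ppg"))) {
    default_channel_schema()
  } else NULL
  rec <- pp_recording(subject_id, channels, annotations = ann,
                      baseline_spans = baseline_spans, schema = schema)
  truth <- list(beat_times = beat_times, scr_times = scr_times,
                segments = cbind(segments, resp_hz = truth_resp),
                baseline_spans = baseline_spans,
                hr0 = hr0, rr0 = rr0, eda0 = eda0)
  list(recording = rec, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Per-subject seeds are derived from the master seed, and per-subject
#' random baselines (resting heart rate, respiratory rate, tonic EDA)
#' induce the inter-subject variability that makes leave-one-subject-out
#' evaluation meaningful.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed.
#' @return List of per-subject lists (`recording`, `truth`).
#' @export
generate_cohort <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "pp_cohort_spec"))
  if (spec$n_subjects < 1L) stop("n_subjects must be at least 1")
  lapply(seq_len(spec$n_subjects), function(i) {
    generate_subject(spec, subject_seed = seed * 1009L + i,
                     subject_id = sprintf("s%02d", i))
  })
}

#' True class of each feature window from generator ground truth
#'
#' @param df Feature data.frame with `t_start`, `t_end`.
#' @param truth A subject's truth list from [generate_subject()].
#' @return Character vector: `BL`, `PL1`-`PL3`, or `NA` for windows that
#'   straddle a segment boundary.
#' @export
true_window_class <- function(df, truth) {
  mid <- (df$t_start + df$t_end) / 2
  out <- rep(NA_character_, length(mid))
  bl <- truth$baseline_spans
  for (i in seq_along(mid)) {
    seg <- which(truth$segments$t_start <= mid[i] &
                   mid[i] < truth$segments$t_end)
    if (length(seg)) {
      out[i] <- truth$segments$class[seg[1L]]
    } else if (any(bl[, 1] <= mid[i] & mid[i] < bl[, 2])) {
      out[i] <- "BL"
    }
  }
  out
}
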