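#' Construct a single-channel biosignal
#'
#' A `pp_signal` holds a uniformly sampled channel: the sample values, the
#' sampling rate in Hz, the start time of the first sample in seconds on the
#' recording clock, and a channel name.
#'
#' @param samples Numeric vector of finite sample values (length >= 1).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds from recording start.
#' @param name Channel identifier, e.g. `"ecg"` or `"emg3"`.
#' @return An object of class `pp_signal`.
#' @export
pp_signal <- function(samples, fs, t0 = 0, name = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("sampling rate fs must be a single positive number")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         name = as.character(name)),
    class = "pp_signal"
  )
}

#' @export
print.pp_signal <- function(x, ...) {
  cat(sprintf("<pp_signal '%s': %d samples @ %g Hz, t0 = %g s (%.1f s)>\n",
              x$name, length(x$samples), x$fs, x$t0,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Sample times of a signal
#'
#' @param sig A [pp_signal()].
#' @return Numeric vector of per-sample times in seconds.
#' @export
signal_times <- function(sig) {
  sig$t0 + (seq_along(sig$samples) - 1) / sig$fs
}

#' Duration of a signal in seconds
#' @param sig A [pp_signal()].
#' @return Length of the signal in seconds (`n / fs`).
#' @export
signal_duration <- function(sig) length(sig$samples) / sig$fs

#' Construct a pain annotation table
#'
#' Self-reported pain on the 11-point numerical rating scale (NRS), integers
#' 0 through 10, each tied to a timestamp on the recording clock.
#'
#' @param t Numeric vector of annotation times in seconds.
#' @param nrs Integer vector of NRS values in 0..10.
#' @return A data.frame with columns `time_s`, `nrs`, sorted by time.
#' @export
pp_annotations <- function(t = numeric(0), nrs = integer(0)) {
  if (length(t) != length(nrs)) stop("t and nrs must have equal length")
  nrs <- as.integer(nrs)
  if (length(nrs) && (any(nrs < 0L) || any(nrs > 10L))) {
    stop("NRS values must lie in 0..10")
  }
  ord <- order(t)
  data.frame(time_s = as.numeric(t)[ord], nrs = nrs[ord])
}

#' Construct a multimodal recording for one subject
#'
#' Bundles all channels of one session: ECG, facial EMG, electrodermal
#' activity (EDA) and photoplethysmography (PPG), together with sparse NRS
#' pain annotations and designated pain-free baseline spans.
#'
#' @param subject_id Subject identifier string.
#' @param channels Named list `modality -> list of pp_signal`. Modalities are
#'   `"ecg"`, `"emg"`, `"eda"`, `"ppg"`. All channels of one modality must
#'   share a sampling rate.
#' @param annotations A data.frame from [pp_annotations()].
#' @param baseline_spans A two-column matrix or data.frame of
#'   (t_start, t_end) spans in seconds during which the subject is at rest
#'   and pain-free; spans must not overlap.
#' @param schema Named integer vector giving the required channel count per
#'   modality; the default matches the study montage (1 ECG, 5 EMG, 1 EDA,
#'   1 PPG). Pass `NULL` to skip the count check.
#' @return An object of class `pp_recording`.
#' @export
pp_recording <- function(subject_id, channels, annotations = pp_annotations(),
                         baseline_spans = NULL,
                         schema = default_channel_schema()) {
  if (!is.list(channels) || is.null(names(channels))) {
    stop("channels must be a named list keyed by modality")
  }
  for (mod in names(channels)) {
    chs <- channels[[mod]]
    if (inherits(chs, "pp_signal")) chs <- list(chs)
    if (!all(vapply(chs, inherits, logical(1), "pp_signal"))) {
      stop("all channels must be pp_signal objects (modality ", mod, ")")
    }
    fss <- vapply(chs, function(s) s$fs, numeric(1))
    if (length(unique(fss)) > 1L) {
      stop("all channels of modality '", mod, "' must share one sampling rate")
    }
    channels[[mod]] <- chs
  }
  if (!is.null(schema)) {
    for (mod in names(schema)) {
      got <- if (mod %in% names(channels)) length(channels[[mod]]) else 0L
      if (got != schema[[mod]]) {
        stop(sprintf("modality '%s' must have %d channel(s), found %d (set schema = NULL to relax)",
                     mod, schema[[mod]], got))
      }
    }
  }
  if (!is.data.frame(annotations) ||
      !all(c("time_s", "nrs") %in% names(annotations))) {
    stop("annotations must be a data.frame with columns time_s, nrs")
  }
  annotations <- pp_annotations(annotations$time_s, annotations$nrs)
  if (is.null(baseline_spans)) {
    baseline_spans <- matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("t_start", "t_end")))
  } else {
    baseline_spans <- as.matrix(baseline_spans)
    colnames(baseline_spans) <- c("t_start", "t_end")
    if (nrow(baseline_spans)) {
      if (any(baseline_spans[, 2] <= baseline_spans[, 1])) {
        stop("baseline spans must have t_end > t_start")
      }
      o <- order(baseline_spans[, 1])
      baseline_spans <- baseline_spans[o, , drop = FALSE]
      if (nrow(baseline_spans) > 1L &&
          any(baseline_spans[-1L, 1] < baseline_spans[-nrow(baseline_spans), 2])) {
        stop("baseline spans must not overlap")
      }
    }
  }
  structure(
    list(subject_id = as.character(subject_id), channels = channels,
         annotations = annotations, baseline_spans = baseline_spans),
    class = "pp_recording"
  )
}

#' Default channel schema (study montage)
#' @return Named integer vector of required channel counts per modality.
#' @export
default_channel_schema <- function() {
  c(ecg = 1L, emg = 5L, eda = 1L, ppg = 1L)
}

#' @export
print.pp_recording <- function(x, ...) {
  nch <- vapply(x$channels, length, integer(1))
  cat(sprintf("<pp_recording subject '%s': %s; %d annotations, %d baseline span(s)>\n",
              x$subject_id,
              paste(sprintf("%s x%d", names(nch), nch), collapse = ", "),
              nrow(x$annotations), nrow(x$baseline_spans)))
  invisible(x)
}

# Canonical modality order used for fusion and reporting.
MODALITIES <- c("ecg", "emg", "eda", "rr")

#' Pain classes
#'
#' The four classes obtained by downsampling NRS: baseline (`BL`) and three
#' increasing pain intensities (`PL1` < `PL2` < `PL3`).
#' @return Character vector of the class labels in order.
#' @export
pain_classes <- function() c("BL", "PL1", "PL2", "PL3")
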