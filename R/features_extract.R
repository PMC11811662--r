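META_COLS <- c("subject_id", "modality", "t_start", "t_end", "window_len",
               "feature_source")

#' Extract handcrafted features from a preprocessed recording
#'
#' Cuts every modality into windows of `window_len` seconds and computes the
#' handcrafted feature sets: 19 time-domain HRV features from ECG (R-peaks
#' are detected once over the whole recording and assigned to windows), 14
#' features per EMG channel (70 over the 5-channel montage), 12 EDA features
#' on the phasic decomposition, and 10 respiration features on the
#' PPG-derived respiratory signal. Windows with any missing value (e.g. too
#' few R-peaks or inhale peaks) are dropped, with a message reporting the
#' count.
#'
#' @param rec A preprocessed [pp_recording()].
#' @param window_len Window length in seconds (5.5 or 10).
#' @param cfg Configuration list.
#' @return Object of class `pp_features`: named list of per-modality
#'   data.frames (`ecg`, `emg`, `eda`, `rr` as available), each holding the
#'   metadata columns `subject_id`, `modality`, `t_start`, `t_end`,
#'   `window_len`, `feature_source`, then the named feature columns.
#' @export
extract_handcrafted <- function(rec, window_len = 10, cfg = default_config()) {
  stopifnot(inherits(rec, "pp_recording"))
  step <- if (is.null(cfg$features$step_s)) window_len else cfg$features$step_s
  out <- list()

  if ("ecg" %in% names(rec$channels)) {
    ecg <- rec$channels$ecg[[1L]]
    nn <- tryCatch(detect_r_peaks(ecg), error = function(e) NULL)
    wins <- sliding_windows(ecg, window_len, step)
    rows <- lapply(wins, function(w) {
      pk <- if (is.null(nn)) numeric(0) else
        nn$r_peak_times[nn$r_peak_times >= w$t_start & nn$r_peak_times < w$t_end]
      f <- if (length(pk) >= 4L) hrv_time_features(diff(pk) * 1000) else
        stats::setNames(rep(NA_real_, 19L), hrv_feature_names())
      names(f) <- paste0("ecg_", names(f))
      c(t_start = w$t_start, t_end = w$t_end, f)
    })
    out$ecg <- finish_modality(rows, rec$subject_id, "ecg", window_len,
                               "handcrafted")
  }

  if ("emg" %in% names(rec$channels)) {
    chans <- rec$channels$emg
    wins_per_ch <- lapply(chans, sliding_windows, window_len = window_len,
                          step_s = step)
    nw <- min(vapply(wins_per_ch, length, integer(1)))
    rows <- lapply(seq_len(nw), function(i) {
      feats <- unlist(lapply(seq_along(chans), function(ci) {
        w <- wins_per_ch[[ci]][[i]]
        f <- emg_features(w$samples, chans[[ci]]$fs,
                          cfg$features$emg_p2p_frame_s)
        stats::setNames(f, paste0("emg", ci, "_", names(f)))
      }))
      w1 <- wins_per_ch[[1L]][[i]]
      c(t_start = w1$t_start, t_end = w1$t_end, feats)
    })
    out$emg <- finish_modality(rows, rec$subject_id, "emg", window_len,
                               "handcrafted")
  }

  if ("eda" %in% names(rec$channels)) {
    eda <- rec$channels$eda[[1L]]
    dec <- eda_decompose(eda)
    wins <- sliding_windows(eda, window_len, step)
    rows <- lapply(wins, function(w) {
      f <- eda_features(w$samples, dec$phasic[w$idx], eda$fs,
                        cfg$features$scr_prominence)
      names(f) <- paste0("eda_", names(f))
      c(t_start = w$t_start, t_end = w$t_end, f)
    })
    out$eda <- finish_modality(rows, rec$subject_id, "eda", window_len,
                               "handcrafted")
  }

  if ("ppg" %in% names(rec$channels)) {
    resp <- tryCatch(derive_respiration(rec$channels$ppg[[1L]]),
                     error = function(e) NULL)
    if (!is.null(resp)) {
      wins <- sliding_windows(resp, window_len, step)
      rows <- lapply(wins, function(w) {
        f <- rr_features(w$samples, resp$fs,
                         cfg$features$inhale_prominence_frac,
                         cfg$features$inhale_min_spacing_s)
        names(f) <- paste0("rr_", names(f))
        c(t_start = w$t_start, t_end = w$t_end, f)
      })
      out$rr <- finish_modality(rows, rec$subject_id, "rr", window_len,
                                "handcrafted")
    }
  }

  structure(out, class = c("pp_features", "list"))
}

finish_modality <- function(rows, subject_id, modality, window_len, source) {
  if (!length(rows)) {
    return(NULL)
  }
  m <- do.call(rbind, rows)
  df <- data.frame(subject_id = subject_id, modality = modality,
                   t_start = m[, "t_start"], t_end = m[, "t_end"],
                   window_len = window_len, feature_source = source,
                   m[, setdiff(colnames(m), c("t_start", "t_end")),
                     drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  n_bad <- sum(!stats::complete.cases(df))
  if (n_bad > 0) {
    message(sprintf("dropping %d %s window(s) with missing features",
                    n_bad, modality))
    df <- df[stats::complete.cases(df), , drop = FALSE]
  }
  if (!nrow(df)) NULL else df
}

#' Numeric feature matrix of a per-modality feature data.frame
#' @param df A per-modality data.frame from [extract_handcrafted()] or
#'   [extract_auto_features()].
#' @return Numeric matrix of the feature columns only.
#' @export
feature_matrix <- function(df) {
  as.matrix(df[, setdiff(names(df), META_COLS), drop = FALSE])
}

#' Write a feature set to CSV files
#'
#' One `features_<modality>.csv` per modality under `path`.
#' @param feats A `pp_features` list.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_features <- function(feats, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(feats)) {
    data.table::fwrite(feats[[mod]],
                       file.path(path, sprintf("features_%s.csv", mod)))
  }
  invisible(path)
}

#' Read a feature set written by [write_features()]
#' @param path Directory of `features_<modality>.csv` files.
#' @return A `pp_features` list.
#' @export
read_features <- function(path) {
  files <- list.files(path, pattern = "^features_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no feature files under ", path)
  out <- list()
  for (f in files) {
    mod <- sub("^features_(.*)\\.csv$", "\\1", basename(f))
    out[[mod]] <- as.data.frame(data.table::fread(f, showProgress = FALSE))
  }
  structure(out, class = c("pp_features", "list"))
}
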