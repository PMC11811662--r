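#' Default pipeline configuration
#'
#' Fully-resolved defaults for every tunable of the pipeline. Any YAML
#' configuration loaded with [load_config()] is merged over these.
#'
#' @return Nested named list of configuration sections.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      ecg = list(band = c(0.1, 250), order = 4),
      emg = list(highpass_hz = 20, notch_hz = c(50, 100), order = 4, q_factor = 30),
      eda = list(ma_window_s = 1, lowpass_hz = 1, order = 4),
      ppg = list(band = c(0.4, 8), order = 4, ma_window_s = 0.25)
    ),
    features = list(
      window_len = 10,          # seconds; 5.5 or 10
      step_s = NULL,            # NULL = window_len (non-overlapping)
      allow_any_window = FALSE,
      emg_p2p_frame_s = 0.5,
      scr_prominence = 0.01,    # microsiemens
      inhale_prominence_frac = 0.2,
      inhale_min_spacing_s = 1.5
    ),
    autoencoder = list(
      arch = "cnn",             # cnn | lstm
      latent_dim = 32L,         # ECG/EDA/RR latent size
      emg_latent_per_channel = 6L,
      epochs = 100L,
      batch_size = 10L,
      learning_rate = 1e-3,
      normalization = "minmax", # minmax | zscore
      resample_len = c(ecg = 512L, emg = 512L, eda = 64L, rr = 128L),
      cnn_channels = c(16L, 32L, 64L),
      cnn_kernel = 3L,
      lstm_hidden = 64L
    ),
    labels = list(
      threshold_s = NULL,       # NULL = window_len used for extraction
      strict_paper_ranges = FALSE,
      weak = list(enabled = FALSE, min_per_class = 10L, knn_k = 5L)
    ),
    augmentation = list(
      smote = list(enabled = FALSE, k_neighbors = 5L)
    ),
    model = list(
      classifier = "svm",       # svm | rf | adaboost | knn
      svm_cost = 1,
      rf_ntree = 100L,
      adaboost_rounds = 50L,
      knn_k = 5L,
      score_unevaluable_folds = FALSE
    ),
    fusion = list(kind = "none", align_tol_s = NULL),  # NULL = window_len
    selection = list(k = 25L),
    seeds = list(master = 0L)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a (possibly empty or partial) YAML file and merges it over
#' [default_config()]. Unknown keys are rejected with the list of valid keys
#' at that level; an absent `seeds.master` falls back to 0 with a warning.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Fully-resolved configuration list of class `pp_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  seed_given <- is.null(path) || !is.null(user$seeds$master)
  cfg <- merge_config(cfg, user, "config")
  validate_config(cfg)
  if (!seed_given) {
    warning("no seeds.master in configuration; defaulting to seed 0")
  }
  structure(cfg, class = c("pp_config", "list"))
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) return(user)
  bad <- setdiff(names(user), names(base))
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s) under %s: %s (valid: %s)",
                 where, paste(bad, collapse = ", "),
                 paste(names(base), collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste(where, k, sep = "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  wl <- cfg$features$window_len
  if (!isTRUE(cfg$features$allow_any_window) && !wl %in% c(5.5, 10)) {
    stop("features.window_len must be 5.5 or 10 seconds ",
         "(set features.allow_any_window to override)")
  }
  if (!cfg$autoencoder$arch %in% c("cnn", "lstm")) {
    stop("autoencoder.arch must be 'cnn' or 'lstm'")
  }
  if (!cfg$fusion$kind %in% c("none", "early", "late")) {
    stop("fusion.kind must be none, early or late")
  }
  invisible(cfg)
}

#' Effective labeling threshold of a configuration
#'
#' The time threshold for matching a feature window to an NRS report
#' defaults to the window length used for extraction.
#'
#' @param cfg A `pp_config`.
#' @return Threshold in seconds.
#' @export
labeling_threshold <- function(cfg) {
  if (is.null(cfg$labels$threshold_s)) cfg$features$window_len
  else cfg$labels$threshold_s
}
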