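#' Extract and label features for a whole cohort
#'
#' For each subject: preprocess, extract handcrafted (or autoencoder)
#' features, and attach strong labels from the subject's annotations and
#' baseline spans. Unlabeled windows are kept (with `NA` label) so weak
#' supervision can be applied inside training folds later.
#'
#' @param cohort List of per-subject lists with a `recording` element
#'   ([generate_cohort()] output, or read recordings wrapped accordingly).
#' @param window_len Window length in seconds.
#' @param cfg Configuration list.
#' @param feature_source `"handcrafted"` or `"auto"`; `"auto"` trains
#'   per-modality autoencoders on the whole cohort — for leakage-free
#'   subject-level evaluation train encoders per fold instead (see
#'   [train_modality_encoders()]).
#' @param modalities Modalities to extract (default all present).
#' @param preprocessed Set `TRUE` when recordings are already filtered.
#' @return A `pp_features` list of stacked per-modality data.frames with
#'   `label` and `provenance` columns.
#' @export
cohort_features <- function(cohort, window_len = 10, cfg = default_config(),
                            feature_source = c("handcrafted", "auto"),
                            modalities = NULL, preprocessed = FALSE) {
  feature_source <- match.arg(feature_source)
  recs <- lapply(cohort, function(s) {
    r <- s$recording
    if (!is.null(modalities)) {
      keep <- intersect(names(r$channels),
                        unique(c(modalities,
                                 if ("rr" %in% modalities) "ppg")))
      r$channels <- r$channels[keep]
    }
    if (preprocessed) r else preprocess_recording(r, cfg)
  })
  encoders <- NULL
  if (feature_source == "auto") {
    encoders <- train_modality_encoders(recs, window_len, cfg,
                                        seed = cfg$seeds$master)
  }
  thr <- labeling_threshold(cfg)
  per_subject <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    feats <- if (feature_source == "handcrafted") {
      extract_handcrafted(rec, window_len, cfg)
    } else {
      extract_auto_features(encoders, rec, window_len, cfg)
    }
    lapply(feats, function(df) {
      assign_strong_labels(df, rec$annotations, thr, rec$baseline_spans,
                           cfg$labels$strict_paper_ranges)
    })
  })
  mods <- unique(unlist(lapply(per_subject, names)))
  out <- lapply(mods, function(m) {
    do.call(rbind, lapply(per_subject, function(s) s[[m]]))
  })
  names(out) <- mods
  structure(out[intersect(MODALITIES, mods)], class = c("pp_features", "list"))
}
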