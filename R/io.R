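#' Read a recording from its on-disk directory format
#'
#' A recording directory holds one CSV per channel (columns `time_s`,
#' `value`), an `annotations.csv` (columns `time_s`, `nrs`, possibly empty),
#' and a `manifest.yaml` listing, per modality, the sampling rate and the
#' channel files in order.
#'
#' @param path Directory containing `manifest.yaml`.
#' @param schema Channel-count schema passed to [pp_recording()]; default is
#'   the study montage, `NULL` relaxes it.
#' @return A [pp_recording()].
#' @export
read_recording <- function(path, schema = default_channel_schema()) {
  manifest_path <- file.path(path, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    stop("not a recording directory: missing ", manifest_path)
  }
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$subject_id) || is.null(man$channels)) {
    stop("manifest must contain subject_id and channels")
  }
  channels <- list()
  for (mod in names(man$channels)) {
    entry <- man$channels[[mod]]
    fs <- as.numeric(entry$fs)
    files <- unlist(entry$files)
    sigs <- lapply(files, function(f) {
      fp <- file.path(path, f)
      if (!file.exists(fp)) stop("missing channel file: ", fp)
      d <- data.table::fread(fp, showProgress = FALSE)
      if (!all(c("time_s", "value") %in% names(d))) {
        stop("channel file ", f, " must have columns time_s, value")
      }
      tt <- d$time_s
      if (length(tt) > 1L && any(diff(tt) <= 0)) {
        stop("non-monotone time column in ", f)
      }
      pp_signal(d$value, fs = fs, t0 = tt[1L],
                name = sub("\\.csv$", "", basename(f)))
    })
    channels[[mod]] <- sigs
  }
  ann_path <- file.path(path, "annotations.csv")
  ann <- pp_annotations()
  if (file.exists(ann_path)) {
    d <- data.table::fread(ann_path, showProgress = FALSE)
    if (nrow(d)) {
      if (!all(c("time_s", "nrs") %in% names(d))) {
        stop("annotations.csv must have columns time_s, nrs")
      }
      tt <- d$time_s
      if (length(tt) > 1L && any(diff(tt) < 0)) {
        stop("non-monotone time column in annotations.csv")
      }
      ann <- pp_annotations(d$time_s, d$nrs)
    }
  }
  spans <- NULL
  if (!is.null(man$baseline_spans)) {
    spans <- do.call(rbind, lapply(man$baseline_spans, as.numeric))
  }
  pp_recording(man$subject_id, channels, annotations = ann,
               baseline_spans = spans, schema = schema)
}

#' Write a recording to the on-disk directory format
#'
#' Inverse of [read_recording()]: values survive the round trip to within
#' 1e-9.
#'
#' @param rec A [pp_recording()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pp_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create recording directory: ", path)
  man <- list(subject_id = rec$subject_id, channels = list())
  for (mod in names(rec$channels)) {
    chs <- rec$channels[[mod]]
    files <- character(length(chs))
    for (i in seq_along(chs)) {
      s <- chs[[i]]
      fname <- if (length(chs) == 1L) paste0(mod, ".csv") else
        sprintf("%s%d.csv", mod, i)
      data.table::fwrite(
        data.frame(time_s = signal_times(s), value = s$samples),
        file.path(path, fname)
      )
      files[i] <- fname
    }
    man$channels[[mod]] <- list(fs = chs[[1L]]$fs, files = as.list(files))
  }
  data.table::fwrite(rec$annotations, file.path(path, "annotations.csv"))
  if (nrow(rec$baseline_spans)) {
    man$baseline_spans <- apply(rec$baseline_spans, 1L, as.list)
  }
  yaml::write_yaml(man, file.path(path, "manifest.yaml"),
                   precision = 15L)
  invisible(path)
}
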