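# Match rows across per-modality feature frames by window midpoint within
# a tolerance, per subject. Returns, per aligned row, the source row index
# in each modality.
align_windows <- function(dfs, align_tol_s) {
  mods <- names(dfs)
  anchor <- dfs[[1L]]
  idx <- matrix(NA_integer_, nrow(anchor), length(mods),
                dimnames = list(NULL, mods))
  idx[, 1L] <- seq_len(nrow(anchor))
  mid_a <- (anchor$t_start + anchor$t_end) / 2
  for (m in mods[-1L]) {
    d <- dfs[[m]]
    mid_m <- (d$t_start + d$t_end) / 2
    for (i in seq_len(nrow(anchor))) {
      same <- which(d$subject_id == anchor$subject_id[i])
      if (!length(same)) next
      dt <- abs(mid_m[same] - mid_a[i])
      j <- which.min(dt)
      if (dt[j] <= align_tol_s + 1e-9) idx[i, m] <- same[j]
    }
  }
  idx[stats::complete.cases(idx), , drop = FALSE]
}

#' Early (feature-level) fusion of modalities
#'
#' Concatenates feature vectors across modalities for windows whose
#' midpoints agree within `align_tol_s` (the window length, matching the
#' labeling threshold). Columns are concatenated in the fixed modality
#' order ECG, EMG, EDA, RR; metadata (and label columns, if present) are
#' taken from the first available modality.
#'
#' @param dfs Named list of per-modality feature data.frames (2 or more).
#' @param align_tol_s Alignment tolerance in seconds.
#' @return A fused data.frame; errors if no rows align.
#' @export
early_fuse <- function(dfs, align_tol_s) {
  dfs <- dfs[intersect(MODALITIES, names(dfs))]
  if (length(dfs) < 2L) stop("early fusion needs at least 2 modalities")
  idx <- align_windows(dfs, align_tol_s)
  if (!nrow(idx)) stop("no alignable windows across modalities")
  meta_label <- intersect(c(META_COLS, "label", "provenance"),
                          names(dfs[[1L]]))
  out <- dfs[[1L]][idx[, 1L], meta_label, drop = FALSE]
  out$modality <- paste(names(dfs), collapse = "+")
  for (m in names(dfs)) {
    fm <- dfs[[m]][idx[, m],
                   setdiff(names(dfs[[m]]),
                           c(META_COLS, "label", "provenance")),
                   drop = FALSE]
    out <- cbind(out, fm)
  }
  rownames(out) <- NULL
  out
}

#' Late (decision-level) fusion of per-modality predictions
#'
#' Majority vote over member labels; ties are broken by the highest mean
#' confidence among the tied classes, then by the fixed member order.
#'
#' @param labels Character vector: one predicted label per member.
#' @param confidences Numeric vector of member confidences (same length).
#' @return The fused label.
#' @export
late_fuse <- function(labels, confidences = rep(1, length(labels))) {
  if (!length(labels)) stop("late fusion needs at least one member")
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  conf <- vapply(top, function(cl) mean(confidences[labels == cl]),
                 numeric(1))
  best <- top[conf == max(conf)]
  if (length(best) == 1L) return(best)
  # fixed member order: first member among the still-tied classes wins
  labels[labels %in% best][1L]
}
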