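#' Map an NRS pain score to its class
#'
#' NRS 0-10 is downsampled to four classes. Under the default rule, 0 maps
#' to baseline (`BL`), 1-3 to `PL1`, 4-6 to `PL2` and 7-10 to `PL3`, so the
#' binary baseline-versus-pain tasks have disjoint classes. With
#' `strict_ranges = TRUE` the literal class ranges are used instead
#' (PL1 covering 0-3), and `BL` only ever arises from designated baseline
#' spans.
#'
#' @param nrs Integer vector of NRS values in 0..10.
#' @param strict_ranges Use the literal 0-3 range for PL1.
#' @return Character vector of classes (`"BL"`, `"PL1"`, `"PL2"`, `"PL3"`).
#' @export
map_nrs_to_class <- function(nrs, strict_ranges = FALSE) {
  nrs <- as.integer(nrs)
  if (any(nrs < 0L | nrs > 10L)) stop("NRS values must lie in 0..10")
  out <- ifelse(nrs <= 3L, "PL1", ifelse(nrs <= 6L, "PL2", "PL3"))
  if (!strict_ranges) out[nrs == 0L] <- "BL"
  out
}

#' Assign strong labels to feature windows by time threshold
#'
#' A window receives the class of the nearest NRS annotation when the
#' annotation lies within `threshold_s` of the window midpoint; windows in
#' a designated baseline span (window fully inside the span) are labeled
#' `BL`. Windows with two equidistant annotations of different classes are
#' discarded (with a message). Everything else stays unlabeled.
#'
#' @param df Per-modality feature data.frame (needs `t_start`, `t_end`).
#' @param annotations Annotation data.frame (`time_s`, `nrs`).
#' @param threshold_s Labeling threshold in seconds; should equal the
#'   window length used for extraction (5.5 or 10).
#' @param baseline_spans Matrix of baseline (t_start, t_end) spans.
#' @param strict_ranges Passed to [map_nrs_to_class()].
#' @return `df` with added columns `label` (`NA` where unlabeled) and
#'   `provenance` (`"strong"` or `NA`), minus discarded tie windows.
#' @export
assign_strong_labels <- function(df, annotations, threshold_s,
                                 baseline_spans = NULL,
                                 strict_ranges = FALSE) {
  mid <- (df$t_start + df$t_end) / 2
  label <- rep(NA_character_, nrow(df))
  drop <- rep(FALSE, nrow(df))
  if (!is.null(annotations) && nrow(annotations)) {
    cls <- map_nrs_to_class(annotations$nrs, strict_ranges)
    for (i in seq_along(mid)) {
      dts <- abs(annotations$time_s - mid[i])
      j <- which(dts <= threshold_s + 1e-9)
      if (!length(j)) next
      best <- min(dts[j])
      nearest <- j[dts[j] <= best + 1e-9]
      u <- unique(cls[nearest])
      if (length(u) == 1L) label[i] <- u else drop[i] <- TRUE
    }
  }
  if (!is.null(baseline_spans) && nrow(baseline_spans)) {
    in_bl <- vapply(seq_along(mid), function(i) {
      any(df$t_start[i] >= baseline_spans[, 1] - 1e-9 &
          df$t_end[i] <= baseline_spans[, 2] + 1e-9)
    }, logical(1))
    label[in_bl & is.na(label) & !drop] <- "BL"
  }
  if (any(drop)) {
    message(sprintf("discarding %d window(s) with equidistant conflicting annotations",
                    sum(drop)))
  }
  df <- df[!drop, , drop = FALSE]
  label <- label[!drop]
  df$label <- label
  df$provenance <- ifelse(is.na(label), NA_character_, "strong")
  df
}

#' Weakly label unlabeled instances with a three-classifier label model
#'
#' Trains an RBF-kernel SVM (with Platt-calibrated probabilities), a random
#' forest and a uniform-weight k-nearest-neighbors classifier on the
#' strong-labeled instances, predicts class probabilities for every
#' unlabeled instance, and assigns the class whose maximum probability
#' across the three members is largest (ties broken by the fixed member
#' priority SVM, then RF, then KNN). Skipped with a warning when the strong
#' set has fewer than 2 classes or fewer than `min_per_class` instances in
#' any class.
#'
#' @param X_strong,y_strong Feature matrix and class vector of the strong
#'   set.
#' @param X_unlabeled Feature matrix of unlabeled instances.
#' @param seed Integer seed.
#' @param min_per_class Minimum strong instances per class (default 10).
#' @param knn_k Neighbors for the KNN member.
#' @return Character vector of weak labels (one per unlabeled row), or
#'   `NULL` when skipped.
#' @export
weak_label <- function(X_strong, y_strong, X_unlabeled, seed = 0L,
                       min_per_class = 10L, knn_k = 5L) {
  y_strong <- as.character(y_strong)
  tab <- table(y_strong)
  if (length(tab) < 2L || any(tab < min_per_class)) {
    warning("weak labeling skipped: degenerate strong-label set")
    return(NULL)
  }
  if (!nrow(X_unlabeled)) return(character(0))
  classes <- sort(names(tab))
  sc <- scale_fit(X_strong)
  Xs <- scale_apply(X_strong, sc)
  Xu <- scale_apply(X_unlabeled, sc)
  set.seed(seed)
  svm_fit <- e1071::svm(Xs, factor(y_strong, levels = classes),
                        kernel = "radial", probability = TRUE)
  p_svm <- attr(stats::predict(svm_fit, Xu, probability = TRUE),
                "probabilities")[, classes, drop = FALSE]
  set.seed(seed)
  rf_fit <- randomForest::randomForest(Xs, factor(y_strong, levels = classes))
  p_rf <- stats::predict(rf_fit, Xu, type = "prob")[, classes, drop = FALSE]
  p_knn <- knn_prob(Xs, y_strong, Xu, k = knn_k)[, classes, drop = FALSE]
  combine_member_probs(list(svm = p_svm, rf = p_rf, knn = p_knn), classes)
}

# Most-confident-prediction combination: each member votes with its single
# most probable class; the member with the highest confidence wins, ties
# resolved by member order (svm > rf > knn).
combine_member_probs <- function(probs, classes) {
  n <- nrow(probs[[1L]])
  vapply(seq_len(n), function(i) {
    conf <- vapply(probs, function(p) max(p[i, ]), numeric(1))
    top <- vapply(probs, function(p) classes[which.max(p[i, ])], character(1))
    top[[which.max(conf)]]  # which.max takes the first (priority) on ties
  }, character(1))
}

# Uniform-weight KNN class probabilities (vote shares among the k nearest).
knn_prob <- function(X_train, y_train, X_test, k = 5L) {
  k <- min(k, nrow(X_train))
  classes <- sort(unique(as.character(y_train)))
  d2 <- outer(rowSums(X_test^2), rep(1, nrow(X_train))) +
    outer(rep(1, nrow(X_test)), rowSums(X_train^2)) -
    2 * X_test %*% t(X_train)
  P <- matrix(0, nrow(X_test), length(classes),
              dimnames = list(NULL, classes))
  for (i in seq_len(nrow(X_test))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(factor(as.character(y_train)[nn], levels = classes))
    P[i, ] <- as.numeric(tab) / k
  }
  P
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

scale_apply <- function(X, sc) {
  sweep(sweep(as.matrix(X), 2L, sc$center, "-"), 2L, sc$scale, "/")
}

#' Label a feature set: strong labels, then optional weak labels
#'
#' Strong labels are assigned first from the annotations and baseline
#' spans; when `weak = TRUE`, remaining unlabeled windows receive a
#' weak-supervision label from [weak_label()] trained on this set's strong
#' instances. Strong labels are never altered by weak labeling.
#'
#' @param df Per-modality feature data.frame.
#' @param annotations Annotation data.frame.
#' @param threshold_s Labeling threshold in seconds.
#' @param baseline_spans Baseline span matrix.
#' @param weak Run weak supervision on the unlabeled remainder.
#' @param seed Integer seed for the label model.
#' @param strict_ranges Passed to [map_nrs_to_class()].
#' @param min_per_class,knn_k Passed to [weak_label()].
#' @return Data.frame of labeled instances (columns `label`, `provenance`);
#'   windows that remain unlabeled are dropped.
#' @export
label_dataset <- function(df, annotations, threshold_s, baseline_spans = NULL,
                          weak = FALSE, seed = 0L, strict_ranges = FALSE,
                          min_per_class = 10L, knn_k = 5L) {
  lab <- assign_strong_labels(df, annotations, threshold_s, baseline_spans,
                              strict_ranges)
  strong <- lab[!is.na(lab$label), , drop = FALSE]
  if (!weak) return(strong)
  unl <- lab[is.na(lab$label), , drop = FALSE]
  if (!nrow(unl)) return(strong)
  wl <- weak_label(feature_matrix(strip_label_cols(strong)), strong$label,
                   feature_matrix(strip_label_cols(unl)), seed = seed,
                   min_per_class = min_per_class, knn_k = knn_k)
  if (is.null(wl)) return(strong)
  unl$label <- wl
  unl$provenance <- "weak"
  rbind(strong, unl)
}

strip_label_cols <- function(df) {
  df[, setdiff(names(df), c("label", "provenance")), drop = FALSE]
}
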