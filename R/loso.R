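#' Specify a binary pain-recognition task
#'
#' @param positive Positive class: `"PL1"`, `"PL2"` or `"PL3"`.
#' @param negative Negative class (default `"BL"`).
#' @param classifier One of `"svm"`, `"rf"`, `"adaboost"`, `"knn"`.
#' @param fusion `"none"` (single modality), `"early"` or `"late"`.
#' @param select_k Features kept by Gini selection (default 25).
#' @param smote Apply SMOTE inside each training fold.
#' @param weak Weak-label unlabeled training-fold windows.
#' @param align_tol_s Fusion alignment tolerance (default: window length of
#'   the data at evaluation time).
#' @return A `pp_task` list.
#' @export
task_spec <- function(positive = c("PL3", "PL1", "PL2"), negative = "BL",
                      classifier = c("svm", "rf", "adaboost", "knn"),
                      fusion = c("none", "early", "late"),
                      select_k = 25L, smote = FALSE, weak = FALSE,
                      align_tol_s = NULL) {
  structure(list(positive = match.arg(positive), negative = negative,
                 classifier = match.arg(classifier),
                 fusion = match.arg(fusion), select_k = as.integer(select_k),
                 smote = isTRUE(smote), weak = isTRUE(weak),
                 align_tol_s = align_tol_s),
            class = "pp_task")
}

# Fit the full training pipeline inside one fold and predict the test rows.
# All fitting (weak labels, selection, SMOTE, classifier, scaling) sees the
# training rows only. Returns labels + confidence for the test rows.
fit_fold <- function(train_df, test_df, task, seed, model_cfg) {
  # weak supervision on the unlabeled training remainder
  if (task$weak) {
    strong <- train_df[!is.na(train_df$label), , drop = FALSE]
    unl <- train_df[is.na(train_df$label), , drop = FALSE]
    if (nrow(unl)) {
      wl <- tryCatch(
        suppressWarnings(weak_label(
          feature_matrix(strip_label_cols(strong)), strong$label,
          feature_matrix(strip_label_cols(unl)), seed = seed)),
        error = function(e) NULL)
      if (!is.null(wl)) {
        unl$label <- wl
        unl$provenance <- "weak"
        train_df <- rbind(strong, unl)
      } else train_df <- strong
    } else train_df <- strong
  } else {
    train_df <- train_df[!is.na(train_df$label), , drop = FALSE]
  }
  keep <- train_df$label %in% c(task$positive, task$negative)
  train_df <- train_df[keep, , drop = FALSE]
  if (length(unique(train_df$label)) < 2L) {
    stop("training fold lacks one of the task classes")
  }
  X <- feature_matrix(strip_label_cols(train_df))
  y <- train_df$label
  sel <- if (ncol(X) > task$select_k) {
    suppressWarnings(gini_select(X, y, k = task$select_k, seed = seed))
  } else seq_len(ncol(X))
  X <- X[, sel, drop = FALSE]
  prov <- train_df$provenance
  if (task$smote) {
    sm <- smote_oversample(X, y, seed = seed)
    X <- sm$X; y <- sm$y
    prov <- c(prov, rep("smote", sum(sm$provenance == "smote")))
  }
  clf <- train_classifier(task$classifier, X, y, seed = seed,
                          cfg = model_cfg)
  Xt <- feature_matrix(strip_label_cols(test_df))[, sel, drop = FALSE]
  pred <- predict_classifier(clf, Xt)
  list(label = pred$label, conf = apply(pred$prob, 1L, max),
       n_weak = sum(prov == "weak"), n_smote = sum(prov == "smote"))
}

#' Leave-one-subject-out evaluation of a binary pain task
#'
#' Each fold holds out all windows of one subject. On the remaining
#' subjects the full training pipeline is fit from scratch — optional weak
#' labeling of their unlabeled windows, Gini feature selection, optional
#' SMOTE, then the task's classifier — and the held-out subject's
#' strong-labeled windows are predicted. Folds whose held-out subject lacks
#' one of the two classes are non-evaluable and excluded from the mean/SD
#' (reported in the result).
#'
#' @param data For `fusion = "none"`: one labeled feature data.frame
#'   (columns `subject_id`, `label`, `provenance`, features; unlabeled rows
#'   have `NA` label and feed weak supervision). For `"early"`/`"late"`: a
#'   named list of such per-modality data.frames.
#' @param task A [task_spec()].
#' @param seed Integer seed used for every random step in every fold.
#' @param model_cfg Classifier hyperparameters
#'   (`default_config()$model`).
#' @return Object of class `pp_eval`: `per_fold` data.frame (subject,
#'   confusion counts, balanced accuracy), `mean`, `sd`, `n_folds`,
#'   `skipped` subjects, and a per-fold `audit` of training-set provenance.
#' @export
loso_evaluate <- function(data, task, seed = 0L,
                          model_cfg = default_config()$model) {
  stopifnot(inherits(task, "pp_task"))
  if (task$fusion == "none") {
    if (!is.data.frame(data)) stop("fusion = 'none' expects one data.frame")
    dfs <- list(data)
  } else {
    if (!is.list(data) || is.data.frame(data) || length(data) < 2L) {
      stop("fusion needs a named list of 2 or more modality data.frames")
    }
    dfs <- data[intersect(MODALITIES, names(data))]
    tol <- if (is.null(task$align_tol_s)) dfs[[1L]]$window_len[1L] else
      task$align_tol_s
    if (task$fusion == "early") {
      dfs <- list(early_fuse(dfs, tol))
    } else {
      idx <- align_windows(dfs, tol)
      if (!nrow(idx)) stop("no alignable windows across modalities")
      dfs <- lapply(seq_along(dfs), function(m) {
        dfs[[m]][idx[, m], , drop = FALSE]
      })
      # labels must agree across aligned rows; use the anchor's
      for (m in seq_along(dfs)[-1L]) {
        dfs[[m]]$label <- dfs[[1L]]$label
        dfs[[m]]$provenance <- dfs[[1L]]$provenance
      }
      names(dfs) <- intersect(MODALITIES, names(data))
    }
  }
  anchor <- dfs[[1L]]
  subjects <- unique(anchor$subject_id)
  strong_eval <- !is.na(anchor$label) & anchor$provenance %in% "strong" &
    anchor$label %in% c(task$positive, task$negative)
  evaluable <- vapply(subjects, function(s) {
    labs <- anchor$label[strong_eval & anchor$subject_id == s]
    length(unique(labs)) == 2L
  }, logical(1))
  if (sum(vapply(subjects, function(s)
    any(anchor$subject_id == s & strong_eval), logical(1))) < 3L) {
    stop("LOSO needs at least 3 subjects with strong labels for the task")
  }
  per_fold <- list(); audit <- list()
  for (s in subjects[evaluable]) {
    test_rows <- which(anchor$subject_id == s & strong_eval)
    train_mask <- anchor$subject_id != s
    if (length(dfs) == 1L) {
      fp <- fit_fold(dfs[[1L]][train_mask, , drop = FALSE],
                     dfs[[1L]][test_rows, , drop = FALSE],
                     task, seed, model_cfg)
      pred <- fp$label
      aud <- list(n_weak = fp$n_weak, n_smote = fp$n_smote)
    } else {
      preds <- lapply(dfs, function(d) {
        fit_fold(d[train_mask, , drop = FALSE],
                 d[test_rows, , drop = FALSE], task, seed, model_cfg)
      })
      pred <- vapply(seq_along(test_rows), function(i) {
        late_fuse(vapply(preds, function(p) p$label[i], character(1)),
                  vapply(preds, function(p) p$conf[i], numeric(1)))
      }, character(1))
      aud <- list(n_weak = sum(vapply(preds, `[[`, numeric(1), "n_weak")),
                  n_smote = sum(vapply(preds, `[[`, numeric(1), "n_smote")))
    }
    y_true <- anchor$label[test_rows]
    cc <- confusion_counts(y_true, pred, task$positive)
    per_fold[[s]] <- data.frame(
      subject_id = s, TP = cc["TP"], FP = cc["FP"], TN = cc["TN"],
      FN = cc["FN"],
      balanced_accuracy = balanced_accuracy(y_true, pred, task$positive),
      row.names = NULL)
    audit[[s]] <- c(aud, list(train_subjects = setdiff(subjects, s),
                              n_test = length(test_rows)))
  }
  pf <- do.call(rbind, per_fold)
  ba <- pf$balanced_accuracy
  structure(
    list(per_fold = pf, mean = mean(ba),
         sd = if (length(ba) > 1L) stats::sd(ba) else NA_real_,
         n_folds = nrow(pf), skipped = subjects[!evaluable],
         task = task, audit = audit),
    class = "pp_eval"
  )
}

#' @export
print.pp_eval <- function(x, ...) {
  cat(sprintf("<pp_eval %s vs %s | %s | fusion=%s>\n", x$task$negative,
              x$task$positive, x$task$classifier, x$task$fusion))
  cat(sprintf("  %d evaluable fold(s)%s; balanced accuracy %.3f (SD %.3f)\n",
              x$n_folds,
              if (length(x$skipped)) paste0(", skipped: ",
                                            paste(x$skipped, collapse = ","))
              else "",
              x$mean, x$sd))
  invisible(x)
}

#' Write an evaluation report to JSON
#' @param ev A `pp_eval`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(ev, path) {
  jsonlite::write_json(
    list(task = unclass(ev$task), per_fold = ev$per_fold,
         mean = ev$mean, sd = ev$sd, n_folds = ev$n_folds,
         skipped = ev$skipped),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
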