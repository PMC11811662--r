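#' Select the most informative features by Gini importance
#'
#' Fits a seeded random forest on the training data and returns the column
#' indices of the `k` features with the highest mean-decrease-in-impurity
#' (Gini) importance. With fewer than `k` columns, all are retained with a
#' warning.
#'
#' @param X_train Numeric feature matrix (training fold only).
#' @param y_train Class vector.
#' @param k Number of features to keep (default 25).
#' @param seed Integer seed.
#' @param ntree Trees in the importance forest.
#' @return Integer vector of selected column indices, highest importance
#'   first.
#' @export
gini_select <- function(X_train, y_train, k = 25L, seed = 0L, ntree = 100L) {
  X_train <- as.matrix(X_train)
  y_train <- factor(as.character(y_train))
  if (nlevels(y_train) < 2L) stop("gini_select needs at least 2 classes")
  if (ncol(X_train) <= k) {
    warning(sprintf("only %d feature(s) available; keeping all", ncol(X_train)))
    return(seq_len(ncol(X_train)))
  }
  set.seed(seed)
  rf <- randomForest::randomForest(X_train, y_train, ntree = ntree,
                                   importance = FALSE)
  imp <- randomForest::importance(rf, type = 2L)[, 1L]
  order(imp, decreasing = TRUE)[seq_len(k)]
}

#' Train a binary pain classifier
#'
#' Supported kinds: RBF-kernel SVM (`"svm"`, C = 1, gamma = 1/ncol scaled),
#' random forest (`"rf"`, 100 trees), AdaBoost over decision stumps
#' (`"adaboost"`, SAMME with 50 rounds of depth-1 rpart trees), and
#' k-nearest neighbors (`"knn"`, k = 5, uniform weights). SVM and KNN
#' consume per-feature standardized inputs (fit on the training data and
#' stored in the model); tree-based models consume raw features. All fits
#' are seeded and deterministic.
#'
#' @param kind One of `"svm"`, `"rf"`, `"adaboost"`, `"knn"`.
#' @param X Numeric feature matrix.
#' @param y Class vector with exactly the task's two classes present.
#' @param seed Integer seed.
#' @param cfg Model section of the configuration (hyperparameters).
#' @return Object of class `pp_classifier` with `predict`/probability
#'   support via [predict_classifier()].
#' @export
train_classifier <- function(kind = c("svm", "rf", "adaboost", "knn"),
                             X, y, seed = 0L, cfg = default_config()$model) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data must contain 2 classes")
  set.seed(seed)
  fit <- switch(kind,
    svm = {
      sc <- scale_fit(X)
      m <- e1071::svm(scale_apply(X, sc), factor(y, levels = classes),
                      kernel = "radial", cost = cfg$svm_cost,
                      probability = TRUE)
      list(model = m, scaler = sc)
    },
    rf = list(model = randomForest::randomForest(
      X, factor(y, levels = classes), ntree = cfg$rf_ntree)),
    adaboost = list(model = adaboost_fit(X, y, classes,
                                         rounds = cfg$adaboost_rounds)),
    knn = list(scaler = scale_fit(X), X = NULL, y = y, k = cfg$knn_k)
  )
  if (kind == "knn") fit$X <- scale_apply(X, fit$scaler)
  structure(list(kind = kind, fit = fit, classes = classes, seed = seed),
            class = "pp_classifier")
}

#' Predict classes and class probabilities
#'
#' @param clf A `pp_classifier` from [train_classifier()].
#' @param X Numeric feature matrix.
#' @return List with `label` (character vector) and `prob` (matrix of class
#'   probabilities, one column per class).
#' @export
predict_classifier <- function(clf, X) {
  X <- as.matrix(X)
  classes <- clf$classes
  prob <- switch(clf$kind,
    svm = {
      Xs <- scale_apply(X, clf$fit$scaler)
      attr(stats::predict(clf$fit$model, Xs, probability = TRUE),
           "probabilities")[, classes, drop = FALSE]
    },
    rf = stats::predict(clf$fit$model, X, type = "prob")[, classes,
                                                         drop = FALSE],
    adaboost = adaboost_prob(clf$fit$model, X),
    knn = knn_prob(clf$fit$X, clf$fit$y, scale_apply(X, clf$fit$scaler),
                   k = clf$fit$k)[, classes, drop = FALSE]
  )
  list(label = classes[max.col(prob, ties.method = "first")], prob = prob)
}

# AdaBoost (SAMME) with depth-1 rpart stumps.
adaboost_fit <- function(X, y, classes, rounds = 50L) {
  n <- nrow(X)
  df <- data.frame(y = factor(y, levels = classes), X, check.names = FALSE)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (r in seq_len(rounds)) {
    st <- rpart::rpart(y ~ ., data = df, weights = w,
                       control = rpart::rpart.control(maxdepth = 1L,
                                                      cp = -1, minsplit = 2L,
                                                      xval = 0L))
    pred <- as.character(stats::predict(st, df, type = "class"))
    err <- sum(w * (pred != y)) / sum(w)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (alpha <= 0) break
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  list(stumps = stumps, alphas = alphas, classes = classes)
}

adaboost_prob <- function(model, X) {
  classes <- model$classes
  df <- data.frame(X, check.names = FALSE)
  score <- matrix(0, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
  for (i in seq_along(model$stumps)) {
    pred <- as.character(stats::predict(model$stumps[[i]], df,
                                        type = "class"))
    for (cl in classes) {
      score[, cl] <- score[, cl] + model$alphas[i] * (pred == cl)
    }
  }
  # softmax over the weighted-vote margins -> probability-like confidences
  e <- exp(score - apply(score, 1L, max))
  e / rowSums(e)
}

#' Balanced accuracy
#'
#' The average of the true-positive rate and the true-negative rate, for a
#' binary task. Both classes must be present in `y_true`.
#'
#' @param y_true,y_pred Character vectors of true and predicted classes.
#' @param positive The positive class; default is the lexicographically
#'   later class (so a pain level is positive against `BL`).
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred, positive = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  if (length(classes) != 2L) {
    stop("balanced accuracy needs both classes present in y_true")
  }
  if (is.null(positive)) positive <- classes[2L]
  tpr <- mean(y_pred[y_true == positive] == positive)
  tnr <- mean(y_pred[y_true != positive] != positive)
  (tpr + tnr) / 2
}

#' Confusion counts for a binary task
#' @param y_true,y_pred Character vectors.
#' @param positive The positive class.
#' @return Named vector (TP, FP, TN, FN).
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  c(TP = sum(y_true == positive & y_pred == positive),
    FP = sum(y_true != positive & y_pred == positive),
    TN = sum(y_true != positive & y_pred != positive),
    FN = sum(y_true == positive & y_pred != positive))
}
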