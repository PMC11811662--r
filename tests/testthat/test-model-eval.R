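test_that("Gini selection finds a perfectly informative column", {
  for (sd in 1:10) {
    set.seed(sd)
    y <- rep(c("BL", "PL2"), each = 30)
    X <- matrix(rnorm(60 * 30), 60, 30)
    X[, 7] <- as.numeric(y == "PL2") + rnorm(60, sd = 0.05)
    sel <- gini_select(X, y, k = 25, seed = sd)
    expect_equal(sel[1], 7)
    expect_length(sel, 25)
  }
  # fewer columns than k: keep all, with a warning
  expect_warning(sel <- gini_select(matrix(rnorm(200), 20, 10),
                                    rep(c("a", "b"), 10), k = 25, seed = 1),
                 "keeping all")
  expect_equal(sel, 1:10)
  # determinism
  set.seed(99)
  X <- matrix(rnorm(50 * 30), 50, 30)
  y <- rep(c("a", "b"), 25)
  expect_identical(gini_select(X, y, seed = 4), gini_select(X, y, seed = 4))
  expect_error(gini_select(X, rep("a", 50), seed = 1), "2 classes")
})

test_that("all four classifier kinds separate linear blobs", {
  set.seed(8)
  n <- 40
  X <- rbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2, 4), n, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("BL", "PL1"), each = n)
  for (kind in c("svm", "rf", "adaboost", "knn")) {
    clf <- train_classifier(kind, X, y, seed = 2)
    pred <- predict_classifier(clf, X)
    expect_gte(balanced_accuracy(y, pred$label, "PL1"), 0.95)
    expect_equal(dim(pred$prob), c(2 * n, 2))
    expect_equal(unname(rowSums(pred$prob)), rep(1, 2 * n),
                 tolerance = 1e-6)
    # determinism of fit + prediction
    clf2 <- train_classifier(kind, X, y, seed = 2)
    expect_identical(predict_classifier(clf2, X)$label, pred$label)
  }
  expect_error(train_classifier("svm", X, rep("BL", 2 * n)), "2 classes")
})

test_that("balanced accuracy equals confusion-matrix arithmetic", {
  expect_equal(balanced_accuracy(c("BL", "PL2"), c("BL", "PL2"), "PL2"), 1)
  # all-positive predictions on a balanced set
  y <- rep(c("BL", "PL2"), each = 10)
  expect_equal(balanced_accuracy(y, rep("PL2", 20), "PL2"), 0.5)
  # TP=8 FN=2 TN=6 FP=4 -> (0.8 + 0.6)/2
  y_true <- c(rep("PL2", 10), rep("BL", 10))
  y_pred <- c(rep("PL2", 8), rep("BL", 2), rep("BL", 6), rep("PL2", 4))
  expect_equal(balanced_accuracy(y_true, y_pred, "PL2"), 0.7)
  expect_equal(confusion_counts(y_true, y_pred, "PL2"),
               c(TP = 8L, FP = 4L, TN = 6L, FN = 2L))
  expect_error(balanced_accuracy(rep("BL", 5), rep("BL", 5)), "both classes")
})

test_that("random confusion tables match the closed-form rate average", {
  set.seed(21)
  for (i in 1:50) {
    y_true <- sample(c("BL", "PL3"), 40, replace = TRUE)
    if (length(unique(y_true)) < 2) next
    y_pred <- sample(c("BL", "PL3"), 40, replace = TRUE)
    cc <- confusion_counts(y_true, y_pred, "PL3")
    want <- (cc["TP"] / (cc["TP"] + cc["FN"]) +
               cc["TN"] / (cc["TN"] + cc["FP"])) / 2
    expect_equal(balanced_accuracy(y_true, y_pred, "PL3"), unname(want))
  }
})

test_that("early fusion aligns by timestamp and concatenates columns", {
  mk <- function(mod, nms, shift = 0) {
    X <- matrix(rnorm(6 * length(nms)), 6,
                dimnames = list(NULL, paste0(mod, "_", nms)))
    data.frame(subject_id = "s", modality = mod,
               t_start = (0:5) * 10 + shift, t_end = (1:6) * 10 + shift,
               window_len = 10, feature_source = "handcrafted", X,
               check.names = FALSE)
  }
  dfs <- list(ecg = mk("ecg", paste0("h", 1:19)),
              emg = mk("emg", paste0("h", 1:70)),
              eda = mk("eda", paste0("h", 1:12)),
              rr = mk("rr", paste0("h", 1:10)))
  fused <- early_fuse(dfs, align_tol_s = 10)
  expect_equal(nrow(fused), 6)
  expect_equal(ncol(feature_matrix(fused)), 111)  # 19 + 70 + 12 + 10
  # modality order is fixed: ECG block first, RR block last
  feats <- setdiff(names(fused), c(painpipe:::META_COLS))
  expect_match(feats[1], "^ecg_")
  expect_match(feats[length(feats)], "^rr_")
  # a modality whose windows lie far outside the tolerance cannot align
  dfs$rr <- mk("rr", paste0("h", 1:10), shift = 1000)
  expect_error(early_fuse(dfs, align_tol_s = 10), "no alignable")
  expect_error(early_fuse(dfs["ecg"], 10), "2 modalities")
})

test_that("late fusion majority-votes with confidence tie-breaks", {
  expect_equal(late_fuse(c("PL2", "PL2", "BL", "PL2"),
                         c(0.6, 0.7, 0.9, 0.5)), "PL2")
  expect_equal(late_fuse(c("BL", "PL2", "BL", "PL2"),
                         c(0.8, 0.6, 0.8, 0.6)), "BL")
  expect_equal(late_fuse("PL1", 0.4), "PL1")
  # full tie on votes and confidence: first member order wins
  expect_equal(late_fuse(c("PL2", "BL"), c(0.5, 0.5)), "PL2")
})

test_that("LOSO evaluation respects its preconditions and fold structure", {
  df <- make_toy_instances(n_subjects = 5, per_class = 8, sep = 3)
  task <- task_spec("PL3", classifier = "rf", select_k = 5)
  ev <- suppressWarnings(loso_evaluate(df, task, seed = 1))
  expect_equal(ev$n_folds, 5)
  expect_equal(nrow(ev$per_fold), 5)
  expect_equal(ev$mean, mean(ev$per_fold$balanced_accuracy))
  expect_gt(ev$mean, 0.9)  # blobs are separable
  # two subjects is below the precondition
  df2 <- df[df$subject_id %in% c("s01", "s02"), ]
  expect_error(suppressWarnings(loso_evaluate(df2, task)), "3 subjects")
  # a subject lacking one class is skipped and reported
  df3 <- df[!(df$subject_id == "s01" & df$label == "PL3"), ]
  ev3 <- suppressWarnings(loso_evaluate(df3, task, seed = 1))
  expect_equal(ev3$n_folds, 4)
  expect_equal(ev3$skipped, "s01")
})

test_that("LOSO never trains on the held-out subject and tests strong-only", {
  df <- make_toy_instances(n_subjects = 4, per_class = 8)
  # add unlabeled and weak-feedable rows
  extra <- df[df$label == "BL", ]
  extra$label <- NA_character_
  extra$provenance <- NA_character_
  extra$t_start <- extra$t_start + 0.5
  full <- rbind(df, extra)
  task <- task_spec("PL3", classifier = "knn", select_k = 5,
                    weak = TRUE, smote = TRUE)
  ev <- suppressWarnings(loso_evaluate(full, task, seed = 2))
  for (s in names(ev$audit)) {
    expect_false(s %in% ev$audit[[s]]$train_subjects)
    # test set size equals that subject's strong task windows
    n_strong <- sum(full$subject_id == s & full$provenance %in% "strong" &
                      full$label %in% c("BL", "PL3"))
    expect_equal(ev$audit[[s]]$n_test, n_strong)
  }
  # weak and SMOTE instances were actually used during training only
  expect_true(all(vapply(ev$audit, function(a) a$n_weak >= 0, logical(1))))
  expect_equal(ev$n_folds, 4)
})

test_that("fused selection yields exactly min(k, total columns) features", {
  df <- make_toy_instances(n_subjects = 3, per_class = 10, n_noise = 30)
  X <- feature_matrix(painpipe:::strip_label_cols(df))
  sel <- gini_select(X, df$label, k = 25, seed = 1)
  expect_length(sel, 25)
  sel2 <- suppressWarnings(gini_select(X[, 1:20], df$label, k = 25,
                                       seed = 1))
  expect_length(sel2, 20)
})
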