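test_that("NRS-to-class mapping partitions the scale into 4 classes", {
  expect_equal(map_nrs_to_class(4), "PL2")
  expect_equal(map_nrs_to_class(10), "PL3")
  expect_equal(map_nrs_to_class(0), "BL")
  expect_equal(map_nrs_to_class(0, strict_ranges = TRUE), "PL1")
  expect_error(map_nrs_to_class(11), "0..10")
  # every NRS maps to exactly one class, and all 4 classes appear
  cls <- map_nrs_to_class(0:10)
  expect_length(cls, 11)
  expect_setequal(unique(cls), pain_classes())
  expect_equal(map_nrs_to_class(1:3), rep("PL1", 3))
  expect_equal(map_nrs_to_class(7:10), rep("PL3", 4))
})

test_that("strong labels follow the midpoint threshold and tie rule", {
  df <- data.frame(subject_id = "s", modality = "rr",
                   t_start = c(95, 125, 95), t_end = c(105, 135, 105),
                   window_len = 10, feature_source = "handcrafted",
                   f1 = 1:3, check.names = FALSE)
  ann <- data.frame(time_s = 100, nrs = 5)
  out <- assign_strong_labels(df[1:2, ], ann, threshold_s = 10)
  expect_equal(out$label, c("PL2", NA))   # midpoints 100 and 130
  expect_equal(out$provenance, c("strong", NA))
  # equidistant conflicting annotations discard the window
  ann2 <- data.frame(time_s = c(95, 105), nrs = c(2, 5))
  expect_message(
    out2 <- assign_strong_labels(df[1, ], ann2, threshold_s = 10),
    "equidistant")
  expect_equal(nrow(out2), 0)
  # baseline spans label windows fully inside them
  out3 <- assign_strong_labels(df, pp_annotations(), threshold_s = 10,
                               baseline_spans = cbind(90, 140))
  expect_equal(out3$label, rep("BL", 3))
})

test_that("the label model picks the most confident member prediction", {
  classes <- c("PL1", "PL2")
  mk <- function(p1) matrix(c(p1, 1 - p1), 1, 2,
                            dimnames = list(NULL, classes))
  # unanimity
  got <- painpipe:::combine_member_probs(
    list(svm = mk(0.2), rf = mk(0.3), knn = mk(0.45)), classes)
  expect_equal(got, "PL2")
  # max-confidence rule: svm says PL1 at 0.9, others PL2 at 0.6/0.55
  got2 <- painpipe:::combine_member_probs(
    list(svm = mk(0.9), rf = mk(0.4), knn = mk(0.45)), classes)
  expect_equal(got2, "PL1")
  # tie on confidence resolves by member priority (svm first)
  got3 <- painpipe:::combine_member_probs(
    list(svm = mk(0.8), rf = mk(0.2), knn = mk(0.2)), classes)
  expect_equal(got3, "PL1")
  # exhaustive check against a brute-force transcription of the rule
  set.seed(4)
  for (i in 1:50) {
    ps <- lapply(1:3, function(j) mk(runif(1)))
    names(ps) <- c("svm", "rf", "knn")
    conf <- vapply(ps, max, numeric(1))
    want <- classes[which.max(ps[[which.max(conf)]][1, ])]
    expect_equal(painpipe:::combine_member_probs(ps, classes), want)
  }
})

test_that("weak labeling is skipped on degenerate strong sets", {
  X <- matrix(rnorm(40), 20, 2)
  expect_warning(
    out <- weak_label(X, rep("PL1", 20), matrix(rnorm(10), 5, 2)),
    "skipped")
  expect_null(out)
  expect_warning(
    weak_label(X, c(rep("PL1", 15), rep("PL2", 5)),
               matrix(rnorm(10), 5, 2)),
    "skipped")  # class below min_per_class
})

test_that("weak labels recover the true class structure above chance", {
  # well-separated blobs: all three members beat chance, so the combined
  # weak labels must beat the majority-class baseline (checked over seeds)
  accs <- vapply(1:20, function(sd) {
    set.seed(sd)
    n <- 30
    Xs <- rbind(matrix(rnorm(n * 2), n, 2),
                matrix(rnorm(n * 2, mean = 2.5), n, 2))
    ys <- rep(c("BL", "PL2"), each = n)
    Xu <- rbind(matrix(rnorm(n * 2), n, 2),
                matrix(rnorm(n * 2, mean = 2.5), n, 2))
    yu <- rep(c("BL", "PL2"), each = n)
    mean(weak_label(Xs, ys, Xu, seed = sd) == yu)
  }, numeric(1))
  expect_gt(mean(accs), 0.5)  # majority baseline on a balanced truth
  expect_gt(mean(accs), 0.8)  # and in fact close to the Bayes rate
})

test_that("label_dataset keeps strong labels invariant under weak mode", {
  df <- make_toy_instances(n_subjects = 2, per_class = 15)
  # hide half the labels to create an unlabeled pool
  unl <- seq(1, nrow(df), by = 2)
  ann_t <- df$t_start[-unl] + 5
  ann <- data.frame(time_s = ann_t + 1000 * 0,
                    nrs = ifelse(df$label[-unl] == "BL", 0, 8))
  base <- df[, setdiff(names(df), c("label", "provenance"))]
  # construct per-row disjoint timestamps so labels land where intended
  base$t_start <- seq_len(nrow(base)) * 100
  base$t_end <- base$t_start + 10
  ann <- data.frame(time_s = base$t_start[-unl] + 5,
                    nrs = ifelse(df$label[-unl] == "BL", 0, 8))
  strong_only <- label_dataset(base, ann, threshold_s = 10)
  with_weak <- label_dataset(base, ann, threshold_s = 10, weak = TRUE,
                             seed = 1)
  expect_gt(nrow(with_weak), nrow(strong_only))
  expect_true(all(with_weak$provenance[seq_len(nrow(strong_only))] ==
                    "strong"))
  m <- merge(strong_only, with_weak, by = "t_start")
  expect_equal(m$label.x, m$label.y)  # no relabeling of ground truth
  expect_setequal(unique(with_weak$provenance), c("strong", "weak"))
})
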