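test_that("the standard case grid has 17 cases in the documented order", {
  cases <- build_cases()
  expect_length(cases, 17)
  expect_identical(
    names(cases),
    c("A-E", "B-E", "C-E", "D-E", "AB-E", "AC-E", "AD-E", "BC-E", "BD-E",
      "CD-E", "ABC-E", "ABD-E", "ACD-E", "BCD-E", "ABCD-E", "AB-CD",
      "AB-CD-E"))
  n2 <- sum(vapply(cases, `[[`, integer(1), "n_classes") == 2L)
  expect_equal(n2, 16)
  expect_equal(cases[["AB-CD-E"]]$n_classes, 3)

  ae <- cases[["A-E"]]
  expect_identical(ae$class_groups, list("A", "E"))
  abcd <- cases[["ABCD-E"]]
  expect_identical(abcd$class_groups[[1]], c("A", "B", "C", "D"))
  expect_identical(abcd$class_groups[[2]], "E")

  expect_error(classification_case("AB-BE"), "disjoint")
  expect_error(classification_case("ABE"), "two groups")
})

test_that("stratified 10-fold split partitions samples and balances classes", {
  y <- rep(1:2, each = 100)
  folds <- kfold_split(y, n_folds = 10, stratified = TRUE, seed = 4)
  expect_length(folds, 10)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:200)          # partition
  expect_true(all(lengths(tests) == 20))
  for (f in folds) {
    expect_identical(as.vector(table(y[f$test])), c(10L, 10L))
    expect_identical(sort(c(f$train, f$test)), 1:200)
  }
  # reproducible from the seed alone
  expect_identical(folds, kfold_split(y, 10, TRUE, seed = 4))
  expect_false(identical(folds, kfold_split(y, 10, TRUE, seed = 5)))
})

test_that("k-fold boundary and error cases behave", {
  y <- rep(1:2, each = 5)
  loo <- kfold_split(y, n_folds = 10, stratified = FALSE, seed = 1)
  expect_true(all(lengths(lapply(loo, `[[`, "test")) == 1))
  expect_error(kfold_split(rep(1:2, c(3, 17)), n_folds = 10, stratified = TRUE),
               "stratified")
  expect_error(kfold_split(y, n_folds = 1), "n_folds")
  # unstratified folds still partition with uneven n
  f <- kfold_split(rep(1:2, c(7, 6)), n_folds = 5, stratified = FALSE, seed = 2)
  expect_identical(sort(unlist(lapply(f, `[[`, "test"))), 1:13)
})

test_that("all four classifiers separate a wide-margin single feature", {
  set.seed(31)
  train_X <- matrix(c(rnorm(30, 0, 0.3), rnorm(30, 10, 0.3)), ncol = 1,
                    dimnames = list(NULL, "f"))
  train_y <- rep(1:2, each = 30)
  test_X <- matrix(c(rnorm(10, 0, 0.3), rnorm(10, 10, 0.3)), ncol = 1,
                   dimnames = list(NULL, "f"))
  truth <- rep(1:2, each = 10)
  for (kind in c("svm", "knn", "nb", "dt")) {
    pred <- fit_predict(classifier_spec(kind, seed = 2), train_X, train_y,
                        test_X)
    expect_identical(pred, truth)
    # determinism under identical spec and seed
    expect_identical(pred, fit_predict(classifier_spec(kind, seed = 2),
                                       train_X, train_y, test_X))
  }
})

test_that("kNN follows k = 3 majority vote with deterministic tie-breaks", {
  train_X <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1,
                    dimnames = list(NULL, "f"))
  train_y <- c(1L, 1L, 1L, 2L, 2L, 2L)
  test_X <- matrix(c(0.05, 5.05), ncol = 1, dimnames = list(NULL, "f"))
  expect_identical(fit_predict(classifier_spec("knn"), train_X, train_y,
                               test_X), c(1L, 2L))
  # vote tie with k = 1 impossible; force a distance tie at k = 1:
  # equidistant neighbours of both classes -> lowest class index wins
  tie_X <- matrix(c(-1, 1), ncol = 1, dimnames = list(NULL, "f"))
  tie_y <- c(2L, 1L)
  at0 <- matrix(0, ncol = 1, dimnames = list(NULL, "f"))
  expect_identical(fit_predict(classifier_spec("knn", k = 1), tie_X, tie_y,
                               at0), 1L)
  expect_error(classifier_spec("knn", k = 2), "odd")
})

test_that("fit_predict enforces its preconditions", {
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(1:2, 5)
  bad <- X; colnames(bad) <- c("a", "c")
  expect_error(fit_predict(classifier_spec("knn"), X, y, bad), "columns")
  expect_error(fit_predict(classifier_spec("knn"), X, rep(1L, 10), X),
               "2 classes")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_predict(classifier_spec("knn"), Xna, y, X), "non-finite")
})

test_that("confusion counts are exact for 2-class and 3-class problems", {
  cm <- confusion_from_predictions(rep(1:2, 6), rep(1:2, 6), positive_class = 2)
  expect_equal(cm$FP + cm$FN, 0)
  expect_equal(cm$CCP, cm$TPT)

  y_true <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0) + 1L
  y_pred <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0) + 1L
  cm <- confusion_from_predictions(y_true, y_pred, positive_class = 2)
  expect_equal(unname(unlist(cm[c("TP", "FN", "TN", "FP")])), c(5, 1, 6, 0))
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, cm$TPT)

  # 3-class: one-vs-rest rows plus full table
  yt <- c(1, 1, 2, 2, 3, 3)
  yp <- c(1, 2, 2, 2, 3, 1)
  cm3 <- confusion_from_predictions(yt, yp, positive_class = 3)
  expect_equal(cm3$CCP, 4)
  expect_equal(cm3$TPT, 6)
  expect_equal(dim(cm3$table), c(3L, 3L))
  expect_equal(sum(cm3$table), 6)
  expect_equal(unname(cm3$one_vs_rest["3", ]), c(1, 0, 4, 1))  # TP FP TN FN
  expect_equal(cm3$TP, 1)

  expect_error(confusion_from_predictions(1:3, 1:2), "lengths differ")
})

test_that("the six metrics match their closed forms on canonical matrices", {
  perfect <- confusion_from_predictions(rep(1:2, 6), rep(1:2, 6), 2)
  m <- compute_metrics(perfect)
  expect_equal(unname(unlist(m[c("accuracy", "sensitivity", "specificity",
                                 "ppv", "npv")])), rep(100, 5))
  expect_equal(m$mcc, 1)

  # all-wrong symmetric matrix: TP=TN=0, FP=FN=6
  wrong <- confusion_from_predictions(rep(1:2, each = 6),
                                      rep(2:1, each = 6), 2)
  m <- compute_metrics(wrong)
  expect_equal(m$accuracy, 0)
  expect_equal(m$mcc, -1)

  # TP=5 FN=1 TN=6 FP=0
  cm <- confusion_from_predictions(
    c(rep(2, 6), rep(1, 6)), c(rep(2, 5), 1, rep(1, 6)), 2)
  m <- compute_metrics(cm)
  expect_equal(m$sensitivity, 100 * 5 / 6, tolerance = 1e-12) # 83.33
  expect_equal(m$specificity, 100)
  expect_equal(m$ppv, 100)
  expect_equal(m$npv, 100 * 6 / 7, tolerance = 1e-12)
  expect_equal(m$mcc, (5 * 6) / sqrt(5 * 6 * 6 * 7), tolerance = 1e-12) # 0.845
  expect_equal(round(m$mcc, 3), 0.845)

  # undefined ratios are NA; zero MCC denominator gives 0
  all_pos_pred <- confusion_from_predictions(rep(1:2, 6), rep(2L, 12), 2)
  m <- compute_metrics(all_pos_pred)
  expect_true(is.na(m$npv))          # TN + FN = 0
  expect_equal(m$mcc, 0)
})

test_that("metric bounds and the MCC=1 equivalence hold over random matrices", {
  set.seed(12)
  for (i in 1:60) {
    yt <- sample(1:2, 40, replace = TRUE)
    yp <- sample(1:2, 40, replace = TRUE)
    if (length(unique(yt)) < 2) next
    m <- compute_metrics(confusion_from_predictions(yt, yp, 2))
    pct <- unlist(m[c("accuracy", "sensitivity", "specificity", "ppv", "npv")])
    pct <- pct[!is.na(pct)]
    expect_true(all(pct >= 0 & pct <= 100))
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
  }
  cm <- confusion_from_predictions(rep(1:2, 10), rep(1:2, 10), 2)
  expect_equal(compute_metrics(cm)$mcc, 1)  # FP=FN=0 with TP,TN>0 <=> MCC=1
})

test_that("run_case cross-validates a separable synthetic problem", {
  ds <- generate_dataset(synth_spec(n_segments_per_class = 30,
                                    segment_length = 1024, seed = 8))
  tab <- build_feature_table(ds, subbands = "D5")
  case <- classification_case("H-S")
  r <- run_case(case, tab, "D5", "MAV", classifier_spec("nb"),
                n_folds = 10, seed = 3)
  expect_s3_class(r, "eval_result")
  expect_gte(r$metrics$accuracy, 95)
  expect_equal(dim(r$per_fold), c(10L, 6L))
  # determinism
  r2 <- run_case(case, tab, "D5", "MAV", classifier_spec("nb"),
                 n_folds = 10, seed = 3)
  expect_identical(r$metrics, r2$metrics)
  # pooled-confusion mode agrees on the perfect-separation problem
  rp <- run_case(case, tab, "D5", "MAV", classifier_spec("knn"),
                 n_folds = 10, seed = 3, pooled = TRUE)
  expect_equal(rp$pooled$accuracy, rp$metrics$accuracy, tolerance = 5)

  expect_error(run_case(classification_case("A-E"), tab, "D5", "MAV",
                        classifier_spec("knn")), "lacks set label")
})

test_that("grid_evaluate enumerates the full grid with one best per cell", {
  ds <- generate_dataset(tiny_spec(n = 12, len = 512, seed = 13))
  tab <- build_feature_table(ds, subbands = c("D4", "D5"))
  grid <- grid_evaluate(tab, cases = list(classification_case("H-S")),
                        classifiers = c("knn", "dt"),
                        features = c("MAV", "STD", "APEN"),
                        n_folds = 4, seed = 5)
  expect_s3_class(grid, "eval_grid")
  expect_equal(nrow(grid), 1 * 2 * 3 * 2)
  expect_equal(anyDuplicated(grid[, c("case", "subband", "feature",
                                      "classifier")]), 0L)
  best <- best_results(grid)
  expect_equal(nrow(best), 2)  # one per (case, classifier)
  expect_setequal(best$classifier, c("knn", "dt"))
  for (i in seq_len(nrow(best))) {
    sub <- grid[grid$classifier == best$classifier[i], ]
    expect_equal(best$accuracy[i], max(sub$accuracy))
  }
})

test_that("label permutation drives accuracy to chance on separable data", {
  ds <- generate_dataset(synth_spec(n_segments_per_class = 30,
                                    segment_length = 1024, seed = 14))
  tab <- build_feature_table(ds, subbands = "D5")
  set.seed(99)
  tab$set_label <- sample(tab$set_label)
  r <- run_case(classification_case("H-S"), tab, "D5", "MAV",
                classifier_spec("knn"), n_folds = 10, seed = 6)
  expect_gte(r$metrics$accuracy, 25)
  expect_lte(r$metrics$accuracy, 75)
})

test_that("more discharge amplitude never hurts D5-MAV accuracy", {
  accs <- vapply(c(60, 150, 400), function(amp) {
    ds <- generate_dataset(synth_spec(n_segments_per_class = 15,
                                      segment_length = 1024,
                                      seizure_amp = amp, seed = 19))
    tab <- build_feature_table(ds, subbands = "D5")
    run_case(classification_case("H-S"), tab, "D5", "MAV",
             classifier_spec("knn"), n_folds = 5, seed = 2)$metrics$accuracy
  }, numeric(1))
  # monotone non-decreasing up to one-run sampling slack
  expect_true(all(diff(accs) >= -5))
  expect_gte(accs[3], 95)
})
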