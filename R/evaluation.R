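#' Stratified k-fold split
#'
#' Partitions sample indices into `n_folds` test sets (default 10),
#' optionally stratified so every fold preserves the class proportions to
#' within one sample. Fold assignment depends only on `seed`.
#'
#' @param labels Integer (or factor) class labels, one per sample.
#' @param n_folds Number of folds (default 10).
#' @param stratified Preserve class proportions per fold? (default TRUE).
#' @param seed Integer seed for the fold assignment.
#' @return List of `n_folds` elements, each `list(train = ..., test = ...)`
#'   of 1-based indices; the test sets partition `seq_along(labels)`.
#' @export
#' @examples
#' folds <- kfold_split(rep(1:2, each = 100), n_folds = 10, seed = 42)
#' lengths(lapply(folds, `[[`, "test"))  # ten test sets of 20
kfold_split <- function(labels, n_folds = 10L, stratified = TRUE, seed = 1L) {
  labels <- as.integer(as.factor(labels))
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > n) {
    stop("n_folds must be in [2, n_samples]; got ", n_folds, " for n = ", n)
  }
  fold_of <- integer(n)
  with_local_seed(seed, {
    if (stratified) {
      for (cl in unique(labels)) {
        members <- which(labels == cl)
        if (length(members) < n_folds) {
          stop("class ", cl, " has only ", length(members),
               " samples; stratified ", n_folds, "-fold CV needs >= ", n_folds)
        }
        perm <- sample(members)
        fold_of[perm] <- rep_len(seq_len(n_folds), length(perm))
      }
    } else {
      fold_of[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  lapply(seq_len(n_folds), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Specify a classifier adapter
#'
#' The four classical classifiers benchmarked by the pipeline. Training and
#' prediction are delegated to established implementations (linear-kernel
#' \pkg{e1071} SVM with cost 1; Gaussian \pkg{e1071} naive Bayes;
#' \pkg{rpart} decision tree with the Gini criterion); the k-nearest-
#' neighbour rule (Euclidean distance, k = 3 by default) is evaluated
#' directly so that ties break deterministically: majority vote, ties
#' resolved by nearest-neighbour distance then lowest class index.
#'
#' @param kind One of `"svm"`, `"knn"`, `"nb"`, `"dt"`.
#' @param k Neighbours for kNN (odd, >= 1; default 3).
#' @param cost SVM soft-margin cost (default 1).
#' @param seed Seed applied around any stochastic component of the
#'   delegated fit.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "knn", "nb", "dt"),
                            k = 3L, cost = 1, seed = 1L) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (kind == "knn" && (k < 1L || k %% 2L == 0L)) {
    stop("kNN requires an odd k >= 1; got ", k)
  }
  structure(list(kind = kind, k = k, cost = cost, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  extra <- switch(x$kind,
                  knn = sprintf(" (k = %d, Euclidean)", x$k),
                  svm = sprintf(" (linear kernel, cost = %g)", x$cost),
                  nb = " (Gaussian)",
                  dt = " (Gini)")
  cat(sprintf("<classifier_spec> %s%s\n", toupper(x$kind), extra))
  invisible(x)
}

# Deterministic k-nearest-neighbour prediction. Ties in the vote are broken
# by the smallest distance to a neighbour of the tied class, then by lowest
# class index.
knn_predict <- function(train_X, train_y, test_X, k) {
  k <- min(k, nrow(train_X))
  pred <- integer(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    d2 <- colSums((t(train_X) - test_X[i, ])^2)
    ord <- order(d2, train_y)             # distance, then class index
    nb <- ord[seq_len(k)]
    votes <- table(train_y[nb])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1L) {
      pred[i] <- top
    } else {
      nearest <- vapply(top, function(cl) min(d2[nb][train_y[nb] == cl]),
                        numeric(1))
      pred[i] <- top[order(nearest, top)][1]
    }
  }
  pred
}

#' Fit a classifier on training rows and predict test rows
#'
#' Adapter over the four classifier kinds: trains on `train_X`/`train_y`
#' and returns one predicted class index per row of `test_X`.
#' Deterministic given the spec's seed.
#'
#' @param classifier A [classifier_spec].
#' @param train_X,test_X Numeric matrices (or data frames) with identical
#'   column sets, all values finite.
#' @param train_y Integer class indices (>= 1), every class represented.
#' @return Integer vector of predicted class indices for `test_X` rows.
#' @export
fit_predict <- function(classifier, train_X, train_y, test_X) {
  stopifnot(inherits(classifier, "classifier_spec"))
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (!identical(colnames(train_X), colnames(test_X)) ||
      ncol(train_X) != ncol(test_X)) {
    stop("train and test feature columns differ")
  }
  if (!all(is.finite(train_X)) || !all(is.finite(test_X))) {
    stop("non-finite feature value passed to classifier")
  }
  train_y <- as.integer(train_y)
  classes <- sort(unique(train_y))
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes")
  }
  yfac <- factor(train_y, levels = classes)
  pred <- with_local_seed(classifier$seed, switch(
    classifier$kind,
    svm = {
      fit <- e1071::svm(x = train_X, y = yfac, kernel = "linear",
                        cost = classifier$cost, scale = apply(train_X, 2,
                                                             stats::sd) > 0)
      as.integer(as.character(predict(fit, test_X)))
    },
    knn = knn_predict(train_X, train_y, test_X, classifier$k),
    nb = {
      fit <- e1071::naiveBayes(x = as.data.frame(train_X), y = yfac)
      as.integer(as.character(predict(fit, as.data.frame(test_X))))
    },
    dt = {
      df <- data.frame(.y = yfac, train_X, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"))
      as.integer(as.character(
        predict(fit, data.frame(test_X, check.names = FALSE), type = "class")
      ))
    }
  ))
  pred
}

#' Confusion matrix from true and predicted class indices
#'
#' For two-class problems returns TP/FP/TN/FN counts with respect to the
#' designated positive class. For more classes returns the full count
#' table plus per-class one-vs-rest TP/FP/TN/FN; `positive_class` selects
#' which one-vs-rest view the scalar fields report. `CCP` (correctly
#' classified patterns) and `TPT` (total patterns) are always filled.
#'
#' @param y_true,y_pred Equal-length integer class index vectors.
#' @param positive_class Class index treated as positive (default: the
#'   largest index, matching the convention that the seizure group is
#'   listed last).
#' @return An object of class `confusion_matrix`: list with `TP`, `FP`,
#'   `TN`, `FN`, `CCP`, `TPT`, `table` (full K x K counts,
#'   true-by-predicted), `one_vs_rest` (per-class count rows) and
#'   `positive_class`.
#' @export
#' @examples
#' cm <- confusion_from_predictions(c(1,1,2,2), c(1,2,2,2), positive_class = 2)
#' cm$TP; cm$FP
confusion_from_predictions <- function(y_true, y_pred,
                                       positive_class = max(y_true)) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ (", length(y_true), " vs ",
         length(y_pred), ")")
  }
  if (length(y_true) == 0L) stop("empty prediction vectors")
  classes <- sort(unique(c(y_true, y_pred, positive_class)))
  tab <- table(factor(y_true, levels = classes),
               factor(y_pred, levels = classes))
  ovr <- t(vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- sum(y_true != cl & y_pred != cl)
    c(TP = tp, FP = fp, TN = tn, FN = fn)
  }, numeric(4)))
  rownames(ovr) <- as.character(classes)
  pos <- as.character(positive_class)
  structure(
    list(
      TP = ovr[pos, "TP"], FP = ovr[pos, "FP"],
      TN = ovr[pos, "TN"], FN = ovr[pos, "FN"],
      CCP = sum(y_true == y_pred), TPT = length(y_true),
      table = tab, one_vs_rest = ovr, positive_class = positive_class
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d/%d correct; positive class %s: TP=%d FP=%d TN=%d FN=%d\n",
              x$CCP, x$TPT, x$positive_class, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Derived classification metrics from a confusion matrix
#'
#' Computes the six standard metrics: accuracy `100*CCP/TPT`, sensitivity
#' `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, positive and negative
#' predictive values `100*TP/(TP+FP)` and `100*TN/(TN+FN)`, and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any 0/0 ratio is reported as `NA`; an MCC with zero denominator is 0.
#'
#' @param cm A `confusion_matrix`, or anything coercible via `$TP` etc.
#' @return Object of class `metrics_report`: named numeric vector-like list
#'   with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percentages) and `mcc`.
#' @export
#' @examples
#' compute_metrics(confusion_from_predictions(rep(1:2, 6), rep(1:2, 6)))
compute_metrics <- function(cm) {
  if (cm$TPT < 1L) stop("confusion matrix has no patterns (TPT = 0)")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  tn <- as.numeric(cm$TN); fn <- as.numeric(cm$FN)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(
    list(
      accuracy = 100 * cm$CCP / cm$TPT,
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp),
      npv = ratio(tn, tn + fn),
      mcc = mcc
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> acc %.2f%%, sens %.2f%%, spec %.2f%%, PPV %.2f%%, NPV %.2f%%, MCC %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv, x$mcc))
  invisible(x)
}

#' Cross-validated evaluation of one case / feature / classifier cell
#'
#' Selects the rows of the feature table belonging to the case's set
#' labels, assigns class indices (last group = positive), splits them with
#' stratified k-fold CV, fits and predicts per fold on the selected
#' feature column(s), computes the six metrics per fold on its test
#' samples, and averages them across folds (`NA` folds for an undefined
#' ratio are dropped from that metric's mean).
#'
#' @param case A `classification_case`.
#' @param table A `feature_table`.
#' @param subband,feature Feature selection: one subband/feature pair, or
#'   both `"all"` for the full feature matrix.
#' @param classifier A [classifier_spec].
#' @param n_folds,stratified,seed Cross-validation settings (defaults:
#'   stratified 10-fold, seed 1).
#' @param pooled Also compute metrics from the pooled confusion matrix of
#'   all test folds (reported in the `pooled` element)?
#' @return Object of class `eval_result`: list with the key tuple, the
#'   fold-averaged `metrics`, per-fold metric matrix `per_fold`, and
#'   optionally `pooled`.
#' @export
run_case <- function(case, table, subband, feature, classifier,
                     n_folds = 10L, stratified = TRUE, seed = 1L,
                     pooled = FALSE) {
  stopifnot(inherits(case, "classification_case"),
            inherits(table, "feature_table"),
            inherits(classifier, "classifier_spec"))
  cols <- feature_columns(table, subband, feature)
  if (length(cols) == 0L) stop("empty feature selection")
  cls <- case_class_index(case, table$set_label)
  present <- unique(table$set_label)
  need <- unlist(case$class_groups)
  if (!all(need %in% present)) {
    stop("feature table lacks set label(s) ",
         paste(setdiff(need, present), collapse = ", "),
         " required by case ", case$name)
  }
  keep <- which(!is.na(cls))
  X <- as.matrix(table[keep, cols, drop = FALSE])
  y <- cls[keep]
  folds <- kfold_split(y, n_folds = n_folds, stratified = stratified,
                       seed = seed)
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                    "mcc")
  per_fold <- matrix(NA_real_, length(folds), length(metric_names),
                     dimnames = list(NULL, metric_names))
  all_true <- integer(0)
  all_pred <- integer(0)
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    pred <- fit_predict(classifier, X[tr, , drop = FALSE], y[tr],
                        X[te, , drop = FALSE])
    cm <- confusion_from_predictions(y[te], pred,
                                     positive_class = case$n_classes)
    m <- compute_metrics(cm)
    per_fold[f, ] <- unlist(m[metric_names])
    all_true <- c(all_true, y[te])
    all_pred <- c(all_pred, pred)
  }
  res <- list(
    case = case$name, subband = subband, feature = feature,
    classifier = classifier$kind,
    metrics = as.list(colMeans(per_fold, na.rm = TRUE)),
    per_fold = per_fold,
    n = length(y)
  )
  if (pooled) {
    res$pooled <- compute_metrics(confusion_from_predictions(
      all_true, all_pred, positive_class = case$n_classes))
  }
  structure(res, class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<eval_result> %s | %s %s | %s: acc %.2f%%, sens %.2f%%, spec %.2f%%, MCC %.3f (n = %d)\n",
    x$case, x$subband, x$feature, toupper(x$classifier),
    m$accuracy, m$sensitivity, m$specificity, m$mcc, x$n))
  invisible(x)
}

#' Evaluate the full case x subband x feature x classifier grid
#'
#' Runs [run_case] for every combination and returns a tidy results table;
#' the per-(case, classifier) best cell by fold-averaged accuracy (ties
#' broken by grid order) is available via [best_results].
#'
#' @param table A `feature_table`.
#' @param cases List of `classification_case` objects (default
#'   [build_cases] restricted to the labels present in `table`).
#' @param classifiers Character vector of classifier kinds or list of
#'   [classifier_spec] objects (default all four).
#' @param subbands,features Grid axes (defaults: the table's subbands; the
#'   seven features).
#' @inheritParams run_case
#' @return Object of class `eval_grid`: a data frame with one row per
#'   grid cell and columns `case`, `subband`, `feature`, `classifier`,
#'   the six metrics, and `n`.
#' @export
grid_evaluate <- function(table, cases = NULL, classifiers = c("svm", "knn", "nb", "dt"),
                          subbands = NULL, features = FEATURE_NAMES,
                          n_folds = 10L, stratified = TRUE, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(subbands)) subbands <- attr(table, "subbands_used")
  if (is.null(cases)) {
    cases <- Filter(function(cs) all(unlist(cs$class_groups) %in%
                                       unique(table$set_label)),
                    build_cases())
  }
  if (length(cases) == 0L || length(classifiers) == 0L ||
      length(subbands) == 0L || length(features) == 0L) {
    stop("grid_evaluate: empty grid axis")
  }
  if (is.character(classifiers)) {
    classifiers <- lapply(classifiers, function(kind)
      classifier_spec(kind, seed = seed))
  }
  rows <- list()
  for (cs in cases) {
    for (sb in subbands) {
      for (ft in features) {
        for (clf in classifiers) {
          r <- run_case(cs, table, sb, ft, clf, n_folds = n_folds,
                        stratified = stratified, seed = seed)
          rows[[length(rows) + 1L]] <- data.frame(
            case = r$case, subband = r$subband, feature = r$feature,
            classifier = r$classifier,
            accuracy = r$metrics$accuracy, sensitivity = r$metrics$sensitivity,
            specificity = r$metrics$specificity, ppv = r$metrics$ppv,
            npv = r$metrics$npv, mcc = r$metrics$mcc, n = r$n,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("eval_grid", "data.frame"))
}

#' Best grid cell per case and classifier
#'
#' Mirrors the per-case "highest accuracy" summaries of benchmark tables:
#' for every (case, classifier) pair, the (subband, feature) cell with the
#' highest fold-averaged accuracy, ties broken by grid order.
#'
#' @param grid An `eval_grid` from [grid_evaluate].
#' @return Data frame with exactly one row per (case, classifier).
#' @export
best_results <- function(grid) {
  stopifnot(inherits(grid, "eval_grid") || is.data.frame(grid))
  df <- as.data.frame(grid)
  split_keys <- interaction(df$case, df$classifier, drop = TRUE)
  picks <- lapply(split(seq_len(nrow(df)), split_keys), function(idx) {
    idx[which.max(df$accuracy[idx])]
  })
  out <- df[sort(unlist(picks)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.eval_grid <- function(x, ...) {
  cat(sprintf("<eval_grid> %d results (%d cases x %d subbands x %d features x %d classifiers)\n",
              nrow(x), length(unique(x$case)), length(unique(x$subband)),
              length(unique(x$feature)), length(unique(x$classifier))))
  NextMethod()
}

#' @export
summary.eval_grid <- function(object, ...) {
  best <- best_results(object)
  cat("Best (subband, feature) per case and classifier, by mean CV accuracy:\n")
  print(as.data.frame(best), digits = 4)
  invisible(best)
}
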