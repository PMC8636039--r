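# Classification stage: stratified cross-validation, held-out testing and the
# augmented-versus-real comparison.

#' Stratified k-fold cross-validation accuracies
#'
#' @param features Window feature matrix.
#' @param labels Class label per window.
#' @param classifiers Named list from [classifier_set()].
#' @param k Folds (default 5).
#' @param seed Seed for the stratified fold assignment and classifier fits.
#' @return Named numeric vector of validation accuracies in percent.
#' @export
train_and_validate <- function(features, labels, classifiers = classifier_set(),
                               k = 5, seed = 1) {
  cnt <- table(labels)
  if (any(cnt < k))
    stop("every class needs at least ", k, " windows (got min ", min(cnt), ")")
  folds <- stratified_folds(labels, k, seed)
  acc <- vapply(names(classifiers), function(nm) {
    cl <- classifiers[[nm]]
    correct <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- cl$fit(features[tr, , drop = FALSE], labels[tr], seed = seed)
      pred <- cl$predict(model, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    100 * correct / length(labels)
  }, 1.0)
  acc
}

#' Stratified fold assignment
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per observation (per-fold class proportions within
#'   one observation of the global proportions).
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  folds <- integer(length(labels))
  withr_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Fit on training windows and evaluate on held-out test windows
#'
#' @param features,labels Training feature matrix and labels.
#' @param test_features,test_labels Held-out test set (disjoint sessions).
#' @param classifiers Named list from [classifier_set()].
#' @param validation Optional named validation accuracies to carry along.
#' @param condition Tag `"real_only"` or `"augmented"`.
#' @param seed Seed passed to classifier fits.
#' @return A `classification_report`: per-classifier validation/test accuracy
#'   (percent) and 4x4 confusion matrices (rows = true class).
#' @export
evaluate_test <- function(features, labels, test_features, test_labels,
                          classifiers = classifier_set(), validation = NULL,
                          condition = "real_only", seed = 1) {
  classes <- sort(unique(c(labels, test_labels)))
  test_acc <- numeric(0)
  confusion <- list()
  for (nm in names(classifiers)) {
    cl <- classifiers[[nm]]
    model <- cl$fit(features, labels, seed = seed)
    pred <- cl$predict(model, test_features)
    test_acc[nm] <- 100 * mean(pred == test_labels)
    confusion[[nm]] <- table(factor(test_labels, classes),
                             factor(pred, classes))
  }
  structure(list(condition = condition, classifiers = names(classifiers),
                 validation = validation, test = test_acc,
                 confusion = confusion, classes = classes),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> condition: %s\n", x$condition))
  df <- data.frame(classifier = x$classifiers,
                   validation = if (is.null(x$validation)) NA
                                else round(x$validation[x$classifiers], 1),
                   test = round(x$test[x$classifiers], 1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare augmented against real-only training
#'
#' Signed per-classifier test-accuracy deltas (augmented minus real-only,
#' improvement positive), their mean and standard deviation, and a pooled
#' two-sample t-test over the conditions' accuracies (validation and test
#' pooled, equal-variance Student form).
#'
#' @param rep_aug,rep_real `classification_report`s over the same classifier
#'   set and test data.
#' @return List with `delta` (named vector, percentage points), `mean_delta`,
#'   `sd_delta`, `t_statistic`, `p_value`.
#' @export
compare_conditions <- function(rep_aug, rep_real) {
  stopifnot(inherits(rep_aug, "classification_report"),
            inherits(rep_real, "classification_report"))
  if (!identical(rep_aug$classifiers, rep_real$classifiers))
    stop("classifier sets differ between the two reports")
  delta <- rep_aug$test[rep_aug$classifiers] - rep_real$test[rep_real$classifiers]
  pool <- function(r) c(r$validation, r$test)
  a <- pool(rep_aug); b <- pool(rep_real)
  tt <- if (sd(a) < 1e-12 && sd(b) < 1e-12)
    list(statistic = c(t = 0), p.value = 1)
  else t.test(a, b, var.equal = TRUE)
  list(delta = delta, mean_delta = mean(delta), sd_delta = sd(delta),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Per-class recall spread of a confusion matrix
#'
#' Max minus min per-class recall (percentage points); used for the class
#' balance check of the augmentation comparison.
#'
#' @param confusion Square confusion matrix, rows = true classes.
#' @return Spread in percentage points.
#' @export
recall_spread <- function(confusion) {
  rec <- 100 * diag(confusion) / pmax(rowSums(confusion), 1)
  max(rec) - min(rec)
}

#' Windowed CSP classification of a train/test split
#'
#' Convenience driver: preprocess (optional), slice windows, fit the CSP bank
#' on the training windows, extract features, cross-validate and test.
#'
#' @param train_ts,test_ts [trial_set()]s with disjoint sessions.
#' @param classifiers Named list from [classifier_set()].
#' @param window_len Window length in samples.
#' @param m CSP filter pairs.
#' @param condition Report tag.
#' @param do_preprocess Apply [preprocess()] to both sets first.
#' @param validate Run the 5-fold validation stage (skip for speed).
#' @param seed RNG seed.
#' @return A `classification_report`.
#' @export
run_classification <- function(train_ts, test_ts,
                               classifiers = classifier_set(),
                               window_len = 100, m = 3,
                               condition = "real_only", do_preprocess = TRUE,
                               validate = TRUE, seed = 1) {
  if (do_preprocess) {
    train_ts <- preprocess(train_ts)
    test_ts <- preprocess(test_ts)
  }
  wb_tr <- slice_windows(train_ts, window_len)
  wb_te <- slice_windows(test_ts, window_len)
  bank <- csp_fit(wb_tr, m = m)
  ftr <- csp_features(wb_tr, bank)
  fte <- csp_features(wb_te, bank)
  val <- if (validate)
    train_and_validate(ftr, wb_tr$label_chr, classifiers, seed = seed)
  else NULL
  evaluate_test(ftr, wb_tr$label_chr, fte, wb_te$label_chr, classifiers,
                validation = val, condition = condition, seed = seed)
}
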