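#' Confusion-table summary for a two-group classifier
#'
#' Exact count arithmetic; the positive class defaults to "patient", so
#' sensitivity is the fraction of patients correctly flagged and
#' specificity the fraction of controls correctly flagged.
#'
#' @param predictions,labels aligned vectors of group labels.
#' @param positive positive-class label.
#' @return list with `accuracy`, `sensitivity`, `specificity` and the 2x2
#'   `confusion` count matrix (rows = truth, cols = prediction).
#' @export
confusion_summary <- function(predictions, labels, positive = "patient") {
  if (length(predictions) != length(labels) || length(labels) == 0)
    stop("predictions and labels must be aligned and non-empty",
         call. = FALSE)
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  pos <- labels == positive
  tp <- sum(pos & predictions == positive)
  fn <- sum(pos & predictions != positive)
  tn <- sum(!pos & predictions != positive)
  fp <- sum(!pos & predictions == positive)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c(positive, "other"),
                                      predicted = c(positive, "other")))
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = confusion)
}

#' RBF-kernel SVM with leave-one-out cross-validation
#'
#' Each subject is predicted by a radial-basis SVM trained on all other
#' subjects. Features are standardised inside each fold using training-fold
#' statistics only (no leakage). Hyperparameters default to cost 1 and
#' gamma 1/p on the standardised features.
#'
#' @param features numeric matrix, one row per subject (typically the four
#'   global metric AUCs).
#' @param labels group label per subject (two classes, each with >= 2
#'   subjects).
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses 1/ncol.
#' @param positive positive-class label for the summary.
#' @return object of class `classification_result`: per-subject
#'   predictions, accuracy, sensitivity, specificity, confusion table and
#'   hyperparameters.
#' @export
loocv_svm <- function(features, labels, cost = 1, gamma = NULL,
                      positive = "patient") {
  features <- as.matrix(features)
  labels <- as.character(labels)
  s <- nrow(features)
  if (length(labels) != s) stop("labels must align with features",
                                call. = FALSE)
  if (any(!is.finite(features))) stop("features must be finite",
                                      call. = FALSE)
  if (min(table(labels)) < 2 || length(unique(labels)) != 2)
    stop("need exactly two classes with >= 2 subjects each", call. = FALSE)
  gamma <- gamma %||% (1 / ncol(features))
  preds <- character(s)
  for (i in seq_len(s)) {
    tr_x <- features[-i, , drop = FALSE]
    tr_y <- factor(labels[-i])
    if (nlevels(droplevels(tr_y)) < 2)
      stop("a class is absent from a training fold", call. = FALSE)
    mu <- colMeans(tr_x)
    sdv <- apply(tr_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    tr_z <- sweep(sweep(tr_x, 2, mu), 2, sdv, `/`)
    te_z <- (features[i, ] - mu) / sdv
    fit <- e1071::svm(x = tr_z, y = tr_y, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    preds[i] <- as.character(stats::predict(fit, matrix(te_z, 1)))
  }
  summ <- confusion_summary(preds, labels, positive = positive)
  structure(
    c(list(per_subject_prediction = preds,
           hyperparameters = list(cost = cost, gamma = gamma,
                                  kernel = "radial")),
      summ),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<LOOCV SVM: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%>\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Label-permutation test for LOOCV accuracy
#'
#' Re-runs the full LOOCV under shuffled labels to form a null accuracy
#' distribution; p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @inheritParams loocv_svm
#' @param n_perm number of label shuffles.
#' @param seed RNG seed.
#' @return list with `observed_accuracy`, `null_accuracies`, `p_value`.
#' @export
accuracy_permutation_test <- function(features, labels, n_perm = 1000,
                                      seed = NULL, cost = 1, gamma = NULL) {
  obs <- loocv_svm(features, labels, cost = cost, gamma = gamma)$accuracy
  labels <- as.character(labels)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      loocv_svm(features, sample(labels), cost = cost,
                gamma = gamma)$accuracy
    }, numeric(1))
  })
  list(observed_accuracy = obs, null_accuracies = null,
       p_value = (1 + sum(null >= obs - 1e-12)) / (1 + n_perm))
}
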