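# Stratified K-fold cross-validation, confusion matrices and the metric
# suite (overall accuracy, error rate, good detection ratio, F1, Matthews
# correlation, mean squared error).

#' Stratified cross-validation folds
#'
#' Partitions indices into `k` folds so that the members of each class are
#' spread as evenly as possible (per-class counts across folds differ by at
#' most 1). Deterministic given the seed.
#'
#' @param labels per-observation class labels
#' @param k fold count (default 10; `k = length(labels)` gives
#'   leave-one-out)
#' @param seed RNG seed
#' @return a `fold_plan`: list with `k`, `seed` and `test_indices`
#'   (list of `k` integer vectors partitioning `seq_along(labels)`)
#' @export
make_folds <- function(labels, k = 10, seed = 1L) {
  labels <- as.character(labels)
  if (k < 2) stop_ecgarr("k must be >= 2")
  if (k > length(labels)) stop_ecgarr("k exceeds the number of observations")
  counts <- table(labels)
  small <- counts[counts < k]
  # k == n is leave-one-out, where per-class counts below k are inherent
  if (length(small) && k < length(labels)) {
    stop_ecgarr("class ", names(small)[1], " has ", small[1],
                " members, fewer than k = ", k)
  }
  with_seed(seed, {
    test <- vector("list", k)
    start <- 0L # rotate the round-robin across classes to balance fold sizes
    for (cl in names(counts)) {
      ids <- sample(which(labels == cl))
      grp <- ((seq_along(ids) + start - 1L) %% k) + 1L
      for (f in seq_len(k)) test[[f]] <- c(test[[f]], ids[grp == f])
      start <- (start + length(ids)) %% k
    }
    structure(list(k = k, seed = seed,
                   test_indices = lapply(test, sort)),
              class = "fold_plan")
  })
}

#' Mean squared error
#'
#' \eqn{\frac{1}{M}\sum_k (G_k - S_k)^2} between an observed and a target
#' sequence of equal length.
#'
#' @param observed numeric vector
#' @param target numeric vector of the same length
#' @return non-negative scalar
#' @export
mse <- function(observed, target) {
  if (length(observed) != length(target)) {
    stop_ecgarr("observed (", length(observed), ") and target (",
                length(target), ") lengths differ")
  }
  if (length(observed) < 1) stop_ecgarr("need at least one value")
  mean((observed - target)^2)
}

#' Confusion matrix for binary labels
#'
#' Counts with the arrhythmia class as positive: TP = abnormal epochs
#' identified as abnormal, TN = normal identified as normal, FP = normal
#' flagged abnormal, FN = abnormal missed.
#'
#' @param true_labels,predicted_labels equal-length binary label vectors
#' @param positive the positive (arrhythmia) class value
#' @return a `confusion_matrix` list with integer fields `tp`, `tn`,
#'   `fp`, `fn`
#' @export
confusion <- function(true_labels, predicted_labels, positive) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop_ecgarr("label vectors must have equal length")
  }
  lev <- unique(c(true_labels, predicted_labels))
  if (!positive %in% lev) stop_ecgarr("positive class not present in labels")
  if (length(lev) > 2) {
    stop_ecgarr("labels must be binary; saw: ", paste(lev, collapse = ", "))
  }
  tpos <- true_labels == positive
  ppos <- predicted_labels == positive
  structure(
    list(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
         fp = sum(!tpos & ppos), fn = sum(tpos & !ppos)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

as_confusion <- function(tp, tn, fp, fn) {
  vals <- c(tp, tn, fp, fn)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop_ecgarr("confusion counts must be non-negative integers")
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_matrix")
}

#' Metric suite from a confusion matrix
#'
#' Computes overall accuracy `OA = (TP+TN)/total * 100`, error rate
#' `ER = (FP+FN)/total * 100`, good detection ratio
#' `GDR = ((TP+TN)-FP)/((TP+TN)+FN) * 100`, `F1 = 2TP/(2TP+FP+FN) * 100`
#' and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' The four percent metrics are evaluated with exact integer arithmetic
#' before half-up rounding to 2 decimals; MCC is rounded half-up to 4
#' decimals and lives on `[-1, 1]`. A zero MCC denominator yields MCC = 0
#' with `degenerate_mcc = TRUE`.
#'
#' @param cm a `confusion_matrix` (or anything with integer `tp`, `tn`,
#'   `fp`, `fn` fields)
#' @return a `metrics_record` list: `OA`, `ER`, `GDR`, `F1`, `MCC`,
#'   `degenerate_mcc`
#' @examples
#' metrics_from_confusion(confusion(rep(c("VT", "NSR"), each = 50),
#'                                  rep(c("VT", "NSR"), each = 50), "VT"))
#' @export
metrics_from_confusion <- function(cm) {
  # doubles: the MCC denominator product overflows 32-bit integers
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  if (any(c(tp, tn, fp, fn) < 0)) stop_ecgarr("negative confusion counts")
  total <- tp + tn + fp + fn
  if (total == 0) stop_ecgarr("empty confusion matrix")
  oa <- round_percent_exact(tp + tn, total)
  # the error rate is reported as the exact complement of OA; computed in
  # hundredth-units so the result is the correctly rounded double
  er <- (10000 - round(oa * 100)) / 100
  gdr <- round_percent_exact(tp + tn - fp, tp + tn + fn)
  f1 <- round_percent_exact(2 * tp, 2 * tp + fp + fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- den == 0
  mcc <- if (degenerate) 0 else {
    round_half_up((tp * tn - fp * fn) /
                    (sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)),
                  4)
  }
  structure(
    list(OA = oa, ER = er, GDR = gdr, F1 = f1, MCC = mcc,
         degenerate_mcc = degenerate),
    class = "metrics_record"
  )
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> OA=%.2f%% ER=%.2f%% GDR=%.2f%% F1=%.2f%% MCC=%.4f\n",
              x$OA, x$ER, x$GDR, x$F1, x$MCC))
  invisible(x)
}

#' Cross-validated evaluation of one classifier family
#'
#' Fits and tests the classifier over a stratified `k`-fold plan, pooling
#' predictions across folds. The pooled confusion equals the sum of
#' per-fold confusions. MSE compares each epoch's decision score against
#' its 0/1-coded label on the family's probability scale when available,
#' otherwise on the thresholded score.
#'
#' @param x feature matrix
#' @param y two-level labels
#' @param family classifier family (see [fit_classifier()])
#' @param config family config
#' @param k folds (default 10)
#' @param seed fold and fit seed
#' @return list with `confusion` (pooled), `metrics`, `mse`,
#'   `fold_confusions`, `error_rate` (fraction in `[0, 1]`)
#' @export
cv_evaluate <- function(x, y, family, config = list(), k = 10, seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  folds <- make_folds(y, k = k, seed = seed)
  pos <- positive_level(unique(y), config$positive)
  pred <- character(length(y))
  score <- numeric(length(y))
  fold_cms <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- folds$test_indices[[f]]
    fit <- fit_classifier(x[-test, , drop = FALSE], y[-test], family,
                          c(config, list(positive = pos)))
    p <- predict(fit, x[test, , drop = FALSE])
    pred[test] <- p$label
    score[test] <- p$score
    fold_cms[[f]] <- confusion(y[test], p$label, pos)
  }
  cm <- confusion(y, pred, pos)
  y01 <- as.numeric(y == pos)
  score_for_mse <- if (family %in% c("nlr", "lr")) score else as.numeric(pred == pos)
  list(confusion = cm, metrics = metrics_from_confusion(cm),
       mse = mse(score_for_mse, y01), fold_confusions = fold_cms,
       error_rate = (cm$fp + cm$fn) / length(y))
}

#' Printed reference tables
#'
#' Loads the fixture of published per-configuration confusion matrices and
#' metric values (dimensionality reduction x selector x tuner x classifier
#' x disease pair) shipped with the package, used to validate the metric
#' engine against an independent source.
#'
#' @return data.frame with columns `selector`, `tuner`, `dr`,
#'   `classifier`, `pair`, `tp`, `tn`, `fp`, `fn`, `avg_mse`, `oa`, `f1`,
#'   `gdr`, `mcc`, `er`
#' @export
printed_reference_tables <- function() {
  path <- system.file("extdata", "printed_tables.csv", package = "ecgarr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
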