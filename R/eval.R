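# Evaluation: confusion counts, sensitivity / specificity / accuracy,
# testing-size-weighted two-fold averaging, and GAR-versus-FAR ROC curves.

#' Confusion counts for binary frame labels
#'
#' @param predicted,truth integer vectors of 0/1 labels, equal length.
#' @return a list of class `ConfusionCounts` with `tp`, `fn`, `tn`, `fp`.
#' @examples
#' confusionCounts(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
confusionCounts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  structure(list(tp = sum(predicted == 1 & truth == 1),
                 fn = sum(predicted == 0 & truth == 1),
                 tn = sum(predicted == 0 & truth == 0),
                 fp = sum(predicted == 1 & truth == 0)),
            class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts: TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sens = 100 TP/(TP+FN), Spec = 100 TN/(TN+FP),
#' Accuracy = 100 (TP+TN)/(TP+TN+FP+FN), all in percent and unrounded.
#' When a class is absent from the test set the corresponding metric is
#' returned as `NA` (flagged, not fabricated).
#'
#' @param counts a `ConfusionCounts` (or list with tp/fn/tn/fp).
#' @return a list of class `MetricsRow` with `sens`, `spec`, `accuracy`
#'   (percent) and the class sizes `P`, `N`.
#' @examples
#' computeMetrics(list(tp = 242, fn = 678, tn = 1539, fp = 100))
#' @export
computeMetrics <- function(counts) {
  P <- counts$tp + counts$fn
  N <- counts$tn + counts$fp
  sens <- if (P >= 1) 100 * counts$tp / P else NA_real_
  spec <- if (N >= 1) 100 * counts$tn / N else NA_real_
  accuracy <- if (P + N >= 1) 100 * (counts$tp + counts$tn) / (P + N)
              else NA_real_
  structure(list(sens = sens, spec = spec, accuracy = accuracy,
                 P = P, N = N),
            class = "MetricsRow")
}

#' @export
print.MetricsRow <- function(x, ...) {
  cat(sprintf("MetricsRow: Sens %s  Spec %s  Accuracy %s (P=%d, N=%d)\n",
              formatMetric(x$sens), formatMetric(x$spec),
              formatMetric(x$accuracy), x$P, x$N))
  invisible(x)
}

formatMetric <- function(v) if (is.na(v)) "undefined" else
  sprintf("%.3f", roundHalfUp(v, 3))

#' Round half away from zero
#'
#' Fixed-tie rounding (x.xxx5 rounds up) used when printing metrics to three
#' decimals; all internal arithmetic stays unrounded.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Testing-size-weighted average of fold metrics
#'
#' Two-fold results are averaged with weights given by the number of testing
#' images, each metric with its own denominator: sensitivity by the
#' positive test counts, specificity by the negative test counts, accuracy
#' by the total test counts. This makes the weighted average of fold metrics
#' identical to the metrics of the pooled confusion counts.
#'
#' @param rows list of `MetricsRow` objects (or lists with sens/spec/
#'   accuracy), one per fold.
#' @param positives integer vector: positive test-frame count per fold.
#' @param negatives integer vector: negative test-frame count per fold.
#' @return a `MetricsRow` with the weighted averages (`P`, `N` are totals).
#' @examples
#' weightedFoldAverage(
#'   list(list(sens = 26.304, spec = 93.899, accuracy = 69.597),
#'        list(sens = 77.417, spec = 54.273, accuracy = 68.584)),
#'   positives = c(920, 3299), negatives = c(1639, 2036))
#' @export
weightedFoldAverage <- function(rows, positives, negatives) {
  k <- length(rows)
  if (length(positives) != k || length(negatives) != k)
    stop("rows, positives and negatives must have equal length")
  if (any(positives <= 0) || any(negatives <= 0))
    stop("fold class counts must be positive")
  sens <- vapply(rows, function(r) r$sens, numeric(1))
  spec <- vapply(rows, function(r) r$spec, numeric(1))
  acc  <- vapply(rows, function(r) r$accuracy, numeric(1))
  totals <- positives + negatives
  structure(list(
    sens = sum(sens * positives) / sum(positives),
    spec = sum(spec * negatives) / sum(negatives),
    accuracy = sum(acc * totals) / sum(totals),
    P = sum(positives), N = sum(negatives)),
    class = "MetricsRow")
}

#' Reconstruct fold accuracy from sensitivity, specificity and class sizes
#'
#' Accuracy is the class-size-weighted mean of sensitivity and specificity:
#' `(sens * P + spec * N) / (P + N)`.
#'
#' @param sens,spec percent metrics.
#' @param positives,negatives class sizes P and N.
#' @return accuracy in percent (unrounded).
#' @examples
#' accuracyFromRates(26.304, 93.899, 920, 1639)   # ~69.597
#' @export
accuracyFromRates <- function(sens, spec, positives, negatives) {
  (sens * positives + spec * negatives) / (positives + negatives)
}

#' GAR-versus-FAR ROC curve
#'
#' Sweeps a decision threshold over the distinct fused positive-class
#' scores (plus sentinels below the minimum and above the maximum); a frame
#' is accepted as positive when its score is >= the threshold. At each
#' threshold FAR = 100 FP/N (negatives wrongly accepted) and
#' GAR = 100 - FRR = 100 TP/P (positives correctly accepted). Points are
#' ordered by increasing FAR and include the (0-region) and (100, 100)
#' endpoints.
#'
#' @param scores numeric vector of fused positive-class scores in [0, 1].
#' @param labels 0/1 truth labels; both classes must be present.
#' @return a data.frame of class `RocCurve` with columns `threshold`,
#'   `far`, `gar` (percent).
#' @examples
#' rocCurve(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
#' @export
rocCurve <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (any(scores < -1e-9 | scores > 1 + 1e-9))
    stop("scores must lie in [0, 1]")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("ROC needs both classes present in the labels")
  thresholds <- sort(unique(c(scores, min(scores) - 1, max(scores) + 1)),
                     decreasing = TRUE)
  pts <- t(vapply(thresholds, function(th) {
    accepted <- scores >= th
    c(far = 100 * sum(accepted & labels == 0) / N,
      gar = 100 * sum(accepted & labels == 1) / P)
  }, c(far = 0, gar = 0)))
  out <- data.frame(threshold = thresholds, far = pts[, "far"],
                    gar = pts[, "gar"])
  out <- out[order(out$far, out$gar), ]
  rownames(out) <- NULL
  class(out) <- c("RocCurve", "data.frame")
  out
}

#' Average ROC curves over folds
#'
#' Linearly interpolates each curve's GAR onto a shared FAR grid
#' (0 to 100 in steps of 1) and averages pointwise — the two-fold ROC is
#' reported as the average of the per-fold curves.
#'
#' @param curves list of `RocCurve` data.frames.
#' @param grid numeric FAR grid; default `seq(0, 100, by = 1)`.
#' @return a `RocCurve` data.frame with columns `far`, `gar` on the grid.
#' @export
averageRocCurves <- function(curves, grid = seq(0, 100, by = 1)) {
  if (length(curves) < 1L) stop("need at least one curve")
  gars <- vapply(curves, function(cv) {
    stats::approx(cv$far, cv$gar, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  out <- data.frame(far = grid, gar = rowMeans(as.matrix(gars)))
  class(out) <- c("RocCurve", "data.frame")
  out
}
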