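# Classification metrics: confusion counts, accuracy, precision/recall, F1,
# AUC, and the evaluate() driver. Multiclass averaging is macro
# (unweighted), with one-vs-rest AUC; per-class metrics with empty
# denominators are returned as NA with a warning and excluded from macro
# averages.

#' Confusion matrix
#'
#' `counts[i, j]` = number of samples with true class `i` predicted as `j`.
#'
#' @param y_true,y_pred Integer (1..K) or factor labels of equal length.
#' @param k Number of classes (inferred if missing).
#' @return A K x K integer matrix of class `confusion_counts`.
#' @export
confusion_counts <- function(y_true, y_pred, k = NULL) {
  lv <- NULL
  if (is.factor(y_true) || is.factor(y_pred)) {
    lv <- levels(as.factor(y_true))
    y_true <- as.integer(as.factor(y_true))
    y_pred <- as.integer(factor(y_pred, levels = lv))
  }
  if (length(y_true) != length(y_pred)) stop_input("label vectors differ in length")
  k <- k %||% max(y_true, y_pred)
  if (any(y_true < 1 | y_true > k) || any(y_pred < 1 | y_pred > k, na.rm = TRUE)) {
    stop_input("labels out of range 1..%d", k)
  }
  m <- matrix(0L, k, k)
  for (i in seq_along(y_true)) {
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  }
  if (!is.null(lv) && length(lv) == k) dimnames(m) <- list(true = lv, pred = lv)
  structure(m, class = c("confusion_counts", "matrix", "array"))
}

#' Accuracy from a confusion matrix
#'
#' Trace over total; for the binary case this is `(TP+TN)/(TP+TN+FP+FN)`.
#'
#' @param counts A [confusion_counts()] matrix.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop_input("cannot compute accuracy of an empty confusion matrix")
  sum(diag(counts)) / n
}

#' One-vs-rest precision and recall for one class
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A zero
#' denominator yields `NA` with a warning (the undefined-metric marker).
#'
#' @param counts A [confusion_counts()] matrix.
#' @param class_k Class index (1..K).
#' @return Named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(counts, class_k = 1) {
  tp <- counts[class_k, class_k]
  fp <- sum(counts[, class_k]) - tp
  fn <- sum(counts[class_k, ]) - tp
  prec <- if (tp + fp == 0) {
    warning("precision undefined for class ", class_k, " (no predicted positives)")
    NA_real_
  } else tp / (tp + fp)
  rec <- if (tp + fn == 0) {
    warning("recall undefined for class ", class_k, " (no actual positives)")
    NA_real_
  } else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' F1 score
#'
#' Harmonic mean `2 P R / (P + R)`; defined as 0 (with a warning) when both
#' are zero. Always lies between `min(P, R)` and `max(P, R)`.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision == 0 && recall == 0) {
    warning("F1 defined as 0 when precision and recall are both 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC built from all score thresholds. Ties are
#' handled so the result equals the pairwise-concordance (Mann-Whitney)
#' statistic: concordant pairs plus half credit for tied pairs, over
#' positives x negatives. For K > 2 supply a score matrix and labels; the
#' macro one-vs-rest average is returned.
#'
#' @param scores Numeric vector (binary; higher = more positive) or n x K
#'   matrix of class scores.
#' @param labels Binary 0/1 (or logical, or two-level factor) vector, or
#'   1..K integers / factor for the multiclass case.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (is.matrix(scores)) {
    k <- ncol(scores)
    y <- as.integer(as.factor(labels))
    aucs <- vapply(seq_len(k), function(j) {
      pos <- as.integer(y == j)
      if (all(pos == 1) || all(pos == 0)) return(NA_real_)
      auc_score(scores[, j], pos)
    }, 1)
    return(mean(aucs, na.rm = TRUE))
  }
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  if (any(!is.finite(scores))) stop_input("scores must be finite")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop_input("AUC undefined: both classes must be present")
  }
  # trapezoid over the tie-grouped ROC; equals the rank statistic
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(1 - y, grp, sum)
  ctp <- c(0, cumsum(tp)); cfp <- c(0, cumsum(fp))
  tpr <- ctp / npos; fpr <- cfp / nneg
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Evaluate a trained classifier
#'
#' Deterministic forward passes over a labelled dataset, returning the
#' five-metric report plus the confusion matrix. Multiclass metrics use
#' macro averaging (recorded in the report).
#'
#' @param model A trained `kct_model` (or any object for which
#'   `predict_fn(model, images)` returns an n x K score matrix).
#' @param images H x W x n image array in `[0, 1]`.
#' @param labels Factor or integer labels.
#' @param predict_fn Prediction function; defaults to
#'   [predict_classifier()].
#' @return An object of class `metrics_report`: a one-row tibble
#'   (`accuracy`, `precision`, `recall`, `f1`, `auc`, `averaging`, `n`)
#'   with per-class metrics in `attr(, "per_class")` and the confusion
#'   matrix in `attr(, "confusion")`.
#' @export
evaluate_model <- function(model, images, labels,
                           predict_fn = predict_classifier) {
  probs <- predict_fn(model, images)
  metrics_from_scores(probs, labels)
}

#' Metrics report from a score matrix
#'
#' @param scores n x K matrix of class scores (rows sum to 1 for
#'   probabilities, not required).
#' @param labels Factor or integer (1..K) labels of length n.
#' @return A `metrics_report`; see [evaluate_model()].
#' @export
metrics_from_scores <- function(scores, labels) {
  y <- as.integer(as.factor(labels))
  k <- ncol(scores)
  pred <- max.col(scores, ties.method = "first")
  cm <- confusion_counts(y, pred, k)
  lv <- levels(as.factor(labels))
  if (length(lv) == k) dimnames(cm) <- list(true = lv, pred = lv)
  per <- lapply(seq_len(k), function(j) {
    pr <- suppressWarnings(precision_recall(cm, j))
    tibble::tibble(class = if (length(lv) == k) lv[j] else as.character(j),
                   precision = pr[["precision"]], recall = pr[["recall"]],
                   f1 = suppressWarnings(f1_score(pr[["precision"]], pr[["recall"]])),
                   support = sum(cm[j, ]))
  })
  per <- do.call(rbind, per)
  auc <- if (k == 2) auc_score(scores[, 2], y == 2) else auc_score(scores, y)
  # binary: report the positive (second) class; multiclass: macro average
  rep <- if (k == 2) {
    tibble::tibble(accuracy = accuracy(cm),
                   precision = per$precision[2], recall = per$recall[2],
                   f1 = per$f1[2], auc = auc,
                   averaging = "binary", n = sum(cm))
  } else {
    tibble::tibble(accuracy = accuracy(cm),
                   precision = mean(per$precision, na.rm = TRUE),
                   recall = mean(per$recall, na.rm = TRUE),
                   f1 = mean(per$f1, na.rm = TRUE),
                   auc = auc, averaging = "macro", n = sum(cm))
  }
  structure(rep, per_class = per, confusion = cm,
            class = c("metrics_report", class(rep)))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d (%s averaging)\n  ACC %.4f  P %.4f  R %.4f  F1 %.4f  AUC %.4f\n",
    x$n, x$averaging, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}
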