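# Test-set metrics for the cross-prediction suite.

#' Confusion matrix with fixed class levels
#'
#' @param truth,pred vectors of true and predicted labels.
#' @param levels class levels defining row/column order (default: sorted
#'   union of both).
#' @return Square integer matrix, rows = true classes, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(truth, pred)))
  table(factor(truth, levels = levels), factor(pred, levels = levels))
}

#' Balanced accuracy from a confusion matrix
#'
#' Mean over classes of the per-class recall (sensitivity); robust to class
#' imbalance and equal to ordinary accuracy on balanced data.
#'
#' @param confusion square non-negative count matrix (rows = true classes).
#' @return A fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  totals <- rowSums(confusion)
  if (any(totals == 0)) stop_config("every true class must be non-empty")
  mean(diag(confusion) / totals)
}

#' Macro-averaged precision, recall and F1
#'
#' Per-class precision and recall averaged with equal class weight; classes
#' never predicted contribute precision 0.
#'
#' @inheritParams balanced_accuracy
#' @return Named vector `precision`, `recall`, `f1`.
#' @export
macro_prf <- function(confusion) {
  confusion <- as.matrix(confusion)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- tp / rowSums(confusion)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  c(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# Macro one-vs-rest AUROC. `prob` is an n x K matrix of class probabilities
# (a vector is treated as P(class 2) for binary problems).
auroc_macro <- function(truth, prob, levels) {
  if (is.null(dim(prob))) prob <- cbind(1 - prob, prob)
  aucs <- vapply(seq_along(levels), function(k) {
    resp <- as.integer(truth == levels[k])
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, k], quiet = TRUE,
                                   direction = "<")))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# Multiclass log loss; labels are 0-based class indices.
mlogloss <- function(label, prob, eps = 1e-15) {
  if (is.null(dim(prob))) prob <- cbind(1 - prob, prob)
  p <- prob[cbind(seq_along(label), label + 1L)]
  -mean(log(pmax(pmin(p, 1 - eps), eps)))
}
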