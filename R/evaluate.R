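# Evaluation: confusion matrix, macro-averaged precision / recall /
# F-measure, the per-class-averaged accuracy variant, plain accuracy, and
# the rank-based Hand-and-Till AUC (one-vs-rest per class).

#' Multiclass confusion matrix
#'
#' @param truth,predicted factors (or characters) of true and predicted
#'   labels.
#' @param levels class level set; defaults to the union of levels observed.
#' @return C x C integer matrix of class \code{confusion_matrix}; rows are
#'   true classes, columns predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels))
    levels <- sort(union(as.character(unique(truth)),
                         as.character(unique(predicted))))
  cm <- table(factor(as.character(truth), levels = levels),
              factor(as.character(predicted), levels = levels))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("true", "predicted")
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

# per-class TP / FP / FN / TN counts
.cm_counts <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- sum(cm) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

.macro_mean <- function(num, den, what) {
  bad <- den == 0
  if (any(bad))
    warning(sum(bad), " class(es) with empty denominator in ", what,
            "; contributing 0")
  v <- ifelse(bad, 0, num / den)
  mean(v)
}

#' Macro-averaged precision
#'
#' Unweighted mean over classes of \eqn{TP_i / (TP_i + FP_i)}. A class never
#' predicted contributes 0 (with a warning).
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @return value in \code{[0, 1]}.
#' @export
macro_precision <- function(cm) {
  k <- .cm_counts(cm)
  .macro_mean(k$tp, k$tp + k$fp, "macro_precision")
}

#' Macro-averaged recall
#'
#' Unweighted mean over classes of \eqn{TP_i / (TP_i + FN_i)}.
#'
#' @inheritParams macro_precision
#' @return value in \code{[0, 1]}.
#' @export
macro_recall <- function(cm) {
  k <- .cm_counts(cm)
  .macro_mean(k$tp, k$tp + k$fn, "macro_recall")
}

#' Macro F-measure
#'
#' \eqn{(\beta^2 + 1) p r / (\beta^2 (p + r))}, returning 0 when
#' \eqn{p + r = 0}.
#'
#' @param p,r macro precision and recall, in \code{[0, 1]}.
#' @param beta recall weight (default 1).
#' @return value in \code{[0, 1]}.
#' @export
macro_f_measure <- function(p, r, beta = 1) {
  stopifnot(p >= 0, p <= 1, r >= 0, r <= 1)
  if (p + r == 0) return(0)
  (beta^2 + 1) * r * p / (beta^2 * (r + p))
}

#' Per-class-averaged accuracy and plain accuracy
#'
#' \code{accuracy_avg} is the mean over classes of
#' \eqn{(TP_i + TN_i) / (TP_i + FN_i + TN_i + FP_i)} — a per-class accuracy
#' including true negatives, averaged with equal class weights. For more
#' than two classes this exceeds the plain trace accuracy (true negatives
#' inflate it), so \code{\link{accuracy_plain}} is always reported
#' alongside.
#'
#' @inheritParams macro_precision
#' @return value in \code{[0, 1]}.
#' @export
accuracy_avg <- function(cm) {
  k <- .cm_counts(cm)
  mean((k$tp + k$tn) / (k$tp + k$fn + k$tn + k$fp))
}

#' @rdname accuracy_avg
#' @export
accuracy_plain <- function(cm) sum(diag(cm)) / sum(cm)

#' Hand-and-Till AUC for one class (one-vs-rest)
#'
#' Ranks all scores ascending (mid-ranks for ties), sums the ranks of the
#' positive examples (\eqn{S_0}) and returns
#' \eqn{(S_0 - n_0(n_0+1)/2) / (n_0 n_1)}, the tie-corrected Mann-Whitney
#' statistic: the probability that a random positive outscores a random
#' negative.
#'
#' @param scores numeric vector of scores for the positive class.
#' @param labels vector of true labels.
#' @param positive the label treated as positive.
#' @return AUC in \code{[0, 1]}, or \code{NA} if either group is empty.
#' @export
hand_till_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n0 <- sum(pos); n1 <- sum(!pos)
  if (n0 == 0L || n1 == 0L) return(NA_real_)
  r <- rank(scores)                      # mid-ranks for ties
  s0 <- sum(r[pos])
  (s0 - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' Evaluate out-of-fold predictions
#'
#' @param pred a \code{fold_predictions} object.
#' @param beta F-measure beta (default 1).
#' @return object of class \code{evaluation_result}: macro precision /
#'   recall / F, \code{accuracy_avg} (per-class-averaged accuracy),
#'   \code{accuracy} (plain), per-class \code{auc}, \code{auc_mean}, and
#'   \code{train_time} in seconds.
#' @export
evaluate_predictions <- function(pred, beta = 1) {
  cm <- confusion_matrix(pred$truth, pred$predicted,
                         levels = levels(pred$truth))
  p <- macro_precision(cm)
  r <- macro_recall(cm)
  auc <- vapply(colnames(pred$scores), function(cl)
    hand_till_auc(pred$scores[, cl], pred$truth, cl), numeric(1))
  structure(list(confusion = cm,
                 precision_M = p, recall_M = r,
                 f_measure_M = macro_f_measure(p, r, beta),
                 accuracy_avg = accuracy_avg(cm),
                 accuracy = accuracy_plain(cm),
                 auc = auc, auc_mean = mean(auc, na.rm = TRUE),
                 train_time = pred$train_time),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_result> precision_M %.4f | recall_M %.4f",
                     " | F_M %.4f | accuracy %.4f | mean AUC %.4f\n"),
              x$precision_M, x$recall_M, x$f_measure_M, x$accuracy,
              x$auc_mean))
  invisible(x)
}
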