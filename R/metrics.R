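# Classification metrics for patch- and slide-level evaluation: confusion
# matrix, accuracy, balanced accuracy, sensitivity, specificity, Cohen's
# kappa, and rank-based ROC/AUC. The positive class is the malignant one
# ("MM", "MALIGNANT", 1 or TRUE).

as_binary01 <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop_invalid("numeric labels must be 0/1")
    return(as.integer(x))
  }
  x <- as.character(x)
  pos <- x %in% c("MM", "MALIGNANT", "1", "TRUE")
  neg <- x %in% c("NM", "NON_MALIGNANT", "0", "FALSE")
  if (!all(pos | neg)) stop_invalid("unrecognized labels: ",
                                    paste(unique(x[!(pos | neg)]), collapse = ", "))
  as.integer(pos)
}

#' Confusion matrix of binary predictions
#'
#' @param true_labels,predicted_labels equal-length binary label vectors
#'   (`MM`/`NM`, `MALIGNANT`/`NON_MALIGNANT`, 0/1 or logical); positive
#'   class is malignant.
#' @return An object of class `"confusion_matrix"` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop_invalid("label vectors must have equal length")
  if (length(true_labels) == 0L) stop_invalid("labels must be non-empty")
  t1 <- as_binary01(true_labels); p1 <- as_binary01(predicted_labels)
  structure(list(tp = sum(t1 == 1L & p1 == 1L),
                 fp = sum(t1 == 0L & p1 == 1L),
                 tn = sum(t1 == 0L & p1 == 0L),
                 fn = sum(t1 == 1L & p1 == 0L)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#'
#' @param tp,fp,tn,fn non-negative counts, total > 0.
#' @return A `"confusion_matrix"`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn == 0)
    stop_invalid("counts must be non-negative with positive total")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity and balanced accuracy are reported as
#' percentages; Cohen's kappa is the chance-corrected agreement
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement from the marginal
#' products. Ratios with a zero denominator are returned as `NaN` and
#' flagged in the `undefined` field.
#'
#' @param cm a `"confusion_matrix"`.
#' @return An object of class `"metrics_report"`: `acc`, `b_acc`, `sen`,
#'   `spe` (percent), `kappa`, and `undefined` (character vector of metric
#'   names that hit a zero denominator).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sen <- ratio(tp, tp + fn)
  spe <- ratio(tn, tn + fp)
  acc <- (tp + tn) / total
  p_o <- acc
  p_e <- ((tp + fn) / total) * ((tp + fp) / total) +
         ((tn + fp) / total) * ((tn + fn) / total)
  kappa <- if (p_e == 1) NaN else (p_o - p_e) / (1 - p_e)
  und <- c(if (is.nan(sen)) "sen", if (is.nan(spe)) "spe",
           if (is.nan(kappa)) "kappa")
  structure(list(acc = 100 * acc, b_acc = 100 * mean(c(sen, spe)),
                 sen = 100 * sen, spe = 100 * spe, kappa = kappa,
                 undefined = und),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc %.1f%%  B_Acc %.1f%%  Sen %.1f%%  Spe %.1f%%  kappa %.3f\n",
              x$acc, x$b_acc, x$sen, x$spe, x$kappa))
  if (!is.null(x$auc)) cat(sprintf("AUC %.3f\n", x$auc))
  if (length(x$undefined))
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random positive scores above a random
#' negative, with ties counted 1/2 — computed from midranks, which equals
#' the trapezoidal area under the ROC curve. ROC points are produced at
#' every distinct score threshold.
#'
#' @param true_labels binary labels, both classes present.
#' @param scores finite numeric scores, larger = more malignant.
#' @return List with `auc` and `roc`, a data.frame of `threshold`, `fpr`,
#'   `tpr` (including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(true_labels, scores) {
  y <- as_binary01(true_labels)
  if (length(y) != length(scores))
    stop_invalid("labels and scores must have equal length")
  if (any(!is.finite(scores))) stop_invalid("scores must be finite")
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop_invalid("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y == 1L & scores >= t) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(y == 0L & scores >= t) / nneg, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}
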