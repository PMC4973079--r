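#' Normalized mean square error of a tracked trace
#'
#' Mean squared error between the estimated and reference traces over the
#' active frames, normalized by the squared peak-to-peak value of the
#' reference over those frames, reported as percent. The squared
#' peak-to-peak denominator makes the measure a dimensionless percentage.
#' Traces are expected on the common 10 Hz time base, with the estimate
#' smoothed by [moving_average5()] upstream.
#'
#' @param estimate,reference numeric traces of equal length.
#' @param active_mask logical mask of active frames (non-empty).
#' @return nMSE in percent.
#' @examples
#' nmse(c(1, 2, 3), c(1, 2, 3), rep(TRUE, 3))
#' @export
nmse <- function(estimate, reference, active_mask = rep(TRUE, length(reference))) {
  stopifnot(length(estimate) == length(reference),
            length(active_mask) == length(reference))
  if (!any(active_mask)) stop("empty active mask", call. = FALSE)
  y <- reference[active_mask]
  e <- estimate[active_mask]
  p2p <- max(y) - min(y)
  if (p2p <= 0) stop("zero peak-to-peak reference", call. = FALSE)
  100 * mean((e - y)^2) / p2p^2
}

#' Pearson correlation between estimate and reference
#'
#' Computed over the active frames; quantifies similarity of signal shape
#' independently of amplitude.
#'
#' @inheritParams nmse
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
pcorr <- function(estimate, reference, active_mask = rep(TRUE, length(reference))) {
  stopifnot(length(estimate) == length(reference),
            length(active_mask) == length(reference))
  y <- reference[active_mask]
  e <- estimate[active_mask]
  if (length(y) < 2) stop("need at least 2 active frames", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(e) == 0) {
    stop("zero variance in trace", call. = FALSE)
  }
  stats::cor(e, y)
}

#' Mean amplitude of false activations (MAFA)
#'
#' Average magnitude of the estimated activation during the silent phases
#' (frames where the finger should be at rest), scaled to percent of
#' `scale`: offline, the reference force peak-to-peak; online, the MVC.
#'
#' @param estimate numeric estimated trace.
#' @param silent_mask logical mask of silent frames (non-empty).
#' @param scale normalization scale (> 0), same units as `estimate`.
#' @return MAFA in percent.
#' @export
mafa <- function(estimate, silent_mask, scale) {
  stopifnot(length(silent_mask) == length(estimate))
  if (!any(silent_mask)) stop("empty silent mask", call. = FALSE)
  if (scale <= 0) stop("zero scale", call. = FALSE)
  100 * mean(abs(estimate[silent_mask])) / scale
}

#' Confusion matrix over movement classes
#'
#' @param truth,decided character vectors of true and decoded movement
#'   classes.
#' @param classes class set (default the canonical nine).
#' @return classes x classes count matrix, rows = truth, cols = decision.
#' @export
confusion_matrix <- function(truth, decided, classes = movement_classes()) {
  stopifnot(length(truth) == length(decided))
  check_movement_class(truth)
  check_movement_class(decided)
  table(factor(truth, classes), factor(decided, classes))
}

#' Classification accuracy
#'
#' The overall success rate: the trace of the confusion matrix divided by
#' the total number of classified instances, in percent.
#'
#' @param confusion square count matrix (rows = truth, cols = decision).
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(confusion)) / total
}

#' One-vs-all sensitivity and specificity per class
#'
#' Each class is collapsed one-vs-rest: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), in percent. Medians across classes
#' summarise a decoder for a given electrode subset.
#'
#' @param confusion square count matrix with dimnames (rows = truth).
#' @param drop_absent drop classes with no true frames instead of raising
#'   an error (default `FALSE`).
#' @return A tibble `class`, `sensitivity`, `specificity` (percent) with
#'   attributes `median_sensitivity` and `median_specificity`; classes
#'   absent from the truth are an error unless `drop_absent`.
#' @export
sensitivity_specificity <- function(confusion, drop_absent = FALSE) {
  confusion <- as.matrix(confusion)
  cls <- rownames(confusion)
  n_true <- rowSums(confusion)
  if (any(n_true == 0)) {
    if (!drop_absent) {
      stop("class absent from truth: ",
           paste(cls[n_true == 0], collapse = ", "), call. = FALSE)
    }
  }
  total <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  out <- tibble::tibble(
    class = cls,
    sensitivity = unname(100 * tp / (tp + fn)),
    specificity = unname(100 * tn / (tn + fp))
  )
  if (drop_absent) out <- out[n_true > 0, ]
  attr(out, "median_sensitivity") <- stats::median(out$sensitivity)
  attr(out, "median_specificity") <- stats::median(out$specificity)
  out
}
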