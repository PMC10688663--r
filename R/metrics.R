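# Training objectives (binary cross-entropy and its focal-weighted variant)
# and pixel-wise segmentation metrics.

#' Loss configuration for focal-weighted binary cross-entropy
#'
#' @param alpha class-balancing weight on foreground pixels, in (0, 1).
#'   Background pixels are weighted `1 - alpha`.  Default 0.25.
#' @param gamma focusing exponent that down-weights easy pixels; `gamma = 0`
#'   with `alpha = 0.5` reduces the loss to half the plain BCE.  Default 2.
#' @param eps probability clip applied before logarithms, in (0, 1e-3].
#' @return An object of class `"loss_config"`.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2, eps = 1e-7) {
  stopifnot(alpha > 0, alpha < 1, gamma >= 0, eps > 0, eps <= 1e-3)
  structure(list(alpha = alpha, gamma = gamma, eps = eps),
            class = "loss_config")
}

#' @keywords internal
check_pixel_batch <- function(y, p) {
  if (length(y) != length(p)) stop("`y` and `p` must be aligned")
  if (length(y) < 1L) stop("empty pixel batch")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary (0/1)")
  if (!all(is.finite(p))) stop("`p` contains non-finite values")
  invisible(TRUE)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` over all pixels, with `p`
#' clipped to `[eps, 1 - eps]` so the logarithms stay finite.
#'
#' @param y binary ground-truth labels (vector or array).
#' @param p predicted foreground probabilities, aligned with `y`.
#' @param eps probability clip.
#' @return A single non-negative number.
#' @examples
#' bce_loss(1, 0.5)  # log(2)
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  check_pixel_batch(y, p)
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  y <- as.numeric(y)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

#' Focal-weighted binary cross-entropy loss
#'
#' The class-imbalance-aware objective used to train the segmentation
#' networks:
#' `-(1/n) * sum(alpha (1-p)^gamma y log p + (1-alpha) p^gamma (1-y) log(1-p))`.
#' Foreground pixels are up-weighted by `alpha`, easy pixels down-weighted
#' by the focal factor.
#'
#' @inheritParams bce_loss
#' @param alpha,gamma,eps see [loss_config()]; scalar arguments take
#'   precedence over `cfg`.
#' @param cfg optionally a [loss_config()] object supplying all three.
#' @return A single non-negative number.
#' @examples
#' wbce_focal_loss(1, 0.5)                 # 0.25 * 0.25 * log(2)
#' wbce_focal_loss(1, 0.5, alpha = 0.5, gamma = 0)  # 0.5 * bce_loss(1, 0.5)
#' @export
wbce_focal_loss <- function(y, p, alpha = 0.25, gamma = 2, eps = 1e-7,
                            cfg = NULL) {
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "loss_config"))
    alpha <- cfg$alpha; gamma <- cfg$gamma; eps <- cfg$eps
  }
  check_pixel_batch(y, p)
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  y <- as.numeric(y)
  -mean(alpha * (1 - p)^gamma * y * log(p) +
          (1 - alpha) * p^gamma * (1 - y) * log1p(-p))
}

# Analytic gradient of the focal loss w.r.t. p (including the 1/n factor),
# zero where the clip is active.  Used by the training loop.
#' @keywords internal
wbce_focal_grad <- function(y, p, alpha = 0.25, gamma = 2, eps = 1e-7) {
  n <- length(p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  gpos <- alpha * (gamma * (1 - pc)^(gamma - 1) * log(pc) - (1 - pc)^gamma / pc)
  gneg <- (1 - alpha) * (pc^gamma / (1 - pc) - gamma * pc^(gamma - 1) * log1p(-pc))
  g <- (y * gpos + (1 - y) * gneg) / n
  g[p != pc] <- 0
  g
}

#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,truth binary masks (0/1) of identical shape.
#' @return An object of class `"confusion_counts"`: a list with integer
#'   fields `TP`, `FP`, `FN`, `TN` summing to the number of pixels.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("`pred` and `truth` must have identical shape")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  structure(list(TP = e1$TP + e2$TP, FP = e1$FP + e2$FP,
                 FN = e1$FN + e2$FN, TN = e1$TN + e2$TN),
            class = "confusion_counts")
}

# Ratio with the empty-agreement convention: 1 when the denominator is zero
# and there is nothing to find or predict (TP = FP = FN = 0), else 0.
#' @keywords internal
safe_ratio <- function(num, den, empty_ok) {
  if (den == 0) return(if (empty_ok) 1 else 0)
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, foreground IoU
#' `TP/(TP+FP+FN)`, F1 `2TP/(2TP+FP+FN)`, overall accuracy
#' `(TP+TN)/total`, and mIoU as the unweighted mean of the foreground and
#' background IoUs.  Zero denominators follow the empty-agreement
#' convention: a metric is 1 when `TP = FP = FN = 0` (empty target matched
#' by empty prediction) and 0 otherwise.
#'
#' @param counts a `"confusion_counts"` object (or list with TP/FP/FN/TN).
#' @return An object of class `"metric_report"`: named list with fields
#'   `precision`, `recall`, `iou`, `f1`, `overall_accuracy`, `miou`.
#' @examples
#' seg_metrics(confusion(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2)))
#' @export
seg_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  stopifnot(all(c(TP, FP, FN, TN) >= 0))
  empty <- (TP + FP + FN) == 0
  precision <- safe_ratio(TP, TP + FP, empty)
  recall <- safe_ratio(TP, TP + FN, empty)
  iou <- safe_ratio(TP, TP + FP + FN, empty)
  f1 <- safe_ratio(2 * TP, 2 * TP + FP + FN, empty)
  total <- TP + FP + FN + TN
  acc <- if (total == 0) 1 else (TP + TN) / total
  bg_empty <- (TN + FP + FN) == 0
  bg_iou <- safe_ratio(TN, TN + FP + FN, bg_empty)
  structure(list(precision = precision, recall = recall, iou = iou, f1 = f1,
                 overall_accuracy = acc, miou = (iou + bg_iou) / 2),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(format_metric_row(x), "\n")
  invisible(x)
}

#' Format a metric report as a comparison-table row
#'
#' Percentages to two decimals for precision, recall and IoU; F1 to two
#' decimals — mirroring the layout used for segmentation comparisons.
#'
#' @param report a `"metric_report"` object.
#' @param label optional row label.
#' @return A single character string.
#' @export
format_metric_row <- function(report, label = NULL) {
  row <- sprintf("P %.2f%%  R %.2f%%  IoU %.2f%%  F1 %.2f",
                 100 * report$precision, 100 * report$recall,
                 100 * report$iou, report$f1)
  if (!is.null(label)) row <- paste0(label, ": ", row)
  row
}
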