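# Evaluation metrics.
#
# Segmentation is scored per slice: Dice overlap, 95th-percentile Hausdorff
# distance between mask boundaries (symmetric: the larger of the two
# directed 95th percentiles, Euclidean distances in physical units), and
# pixel-level precision/recall. Classification is scored per patient with
# mutant as the positive class.

check_masks <- function(pred, true) {
  if (!identical(dim(pred), dim(true)))
    stop("shape mismatch: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(true), collapse = "x"))
  if (!all(pred %in% c(0, 1)) || !all(true %in% c(0, 1)))
    stop("masks must be binary")
}

#' Dice similarity score
#'
#' \code{2|X ∩ Y| / (|X| + |Y|)} = \code{2TP / (2TP + FN + FP)}.
#' Two empty masks score 1.0 by convention.
#'
#' @param pred,true binary matrices of identical shape.
#' @return scalar in [0, 1].
#' @export
dice_score <- function(pred, true) {
  check_masks(pred, true)
  s <- sum(pred) + sum(true)
  if (s == 0) return(1.0)
  2 * sum(pred * true) / s
}

# foreground pixels with at least one 4-neighbour outside the foreground
# (image border counts as background)
boundary_mask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], 0)
  dn <- rbind(0, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], 0)
  rt <- cbind(0, m[, -nc, drop = FALSE])
  m == 1 & (up == 0 | dn == 0 | lf == 0 | rt == 0)
}

#' 95th-percentile Hausdorff distance
#'
#' Extracts the boundary pixels of both masks (foreground pixels with a
#' background 4-neighbour; the image edge counts as background), computes
#' both directed boundary-to-boundary distance sets in physical units, and
#' returns the larger of the two 95th percentiles (linear interpolation
#' between order statistics). Identical masks give 0. If exactly one mask is
#' empty the image diagonal (in mm) is returned as a sentinel and the result
#' carries attribute \code{degenerate = TRUE}; two empty masks give 0.
#'
#' @param pred,true binary matrices of identical shape.
#' @param spacing pixel size \code{c(row_mm, col_mm)}.
#' @return distance in mm.
#' @export
hd95 <- function(pred, true, spacing = c(1, 1)) {
  check_masks(pred, true)
  np <- sum(pred); nt <- sum(true)
  if (np == 0 && nt == 0) return(0)
  if (np == 0 || nt == 0) {
    d <- sqrt((nrow(pred) * spacing[1])^2 + (ncol(pred) * spacing[2])^2)
    attr(d, "degenerate") <- TRUE
    return(d)
  }
  bp <- which(boundary_mask(pred), arr.ind = TRUE)
  bt <- which(boundary_mask(true), arr.ind = TRUE)
  dr <- outer(bp[, 1] * spacing[1], bt[, 1] * spacing[1], "-")
  dc <- outer(bp[, 2] * spacing[2], bt[, 2] * spacing[2], "-")
  d2 <- dr * dr + dc * dc
  d_pt <- sqrt(apply(d2, 1, min))   # pred boundary -> true boundary
  d_tp <- sqrt(apply(d2, 2, min))   # true boundary -> pred boundary
  max(stats::quantile(d_pt, 0.95, names = FALSE, type = 7),
      stats::quantile(d_tp, 0.95, names = FALSE, type = 7))
}

#' Pixel-level precision and recall
#'
#' Precision \code{TP/(TP+FP)} and recall \code{TP/(TP+FN)}. An empty
#' denominator scores 1.0 when the complementary reference set is also empty
#' (nothing to find, nothing claimed), else 0.0.
#'
#' @param pred,true binary matrices of identical shape.
#' @return named vector \code{c(precision = , recall = )}.
#' @export
pixel_precision_recall <- function(pred, true) {
  check_masks(pred, true)
  tp <- sum(pred * true)
  fp <- sum(pred * (1 - true))
  fn <- sum((1 - pred) * true)
  precision <- if (tp + fp == 0) as.numeric(tp + fn == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) as.numeric(tp + fp == 0) else tp / (tp + fn)
  c(precision = precision, recall = recall)
}

#' Confusion counts for binary labels
#'
#' @param preds,truths equal-length binary vectors, 1 = mutant (positive).
#' @return named integer vector \code{c(tp, fp, fn, tn)}.
#' @export
confusion_counts <- function(preds, truths) {
  if (length(preds) != length(truths) || length(preds) == 0)
    stop("preds and truths must be non-empty and of equal length")
  if (!all(preds %in% c(0, 1)) || !all(truths %in% c(0, 1)))
    stop("labels must be binary")
  c(tp = sum(preds == 1 & truths == 1),
    fp = sum(preds == 1 & truths == 0),
    fn = sum(preds == 0 & truths == 1),
    tn = sum(preds == 0 & truths == 0))
}

#' Patient-level classification metrics
#'
#' Accuracy, precision, recall and F1 with mutant (1) as the positive class;
#' \code{F1 = 2PR/(P+R)} (0 when both P and R are 0). Empty-denominator
#' conventions as in [pixel_precision_recall()].
#'
#' @param preds,truths equal-length binary label vectors.
#' @return named vector \code{c(accuracy, precision, recall, f1)}.
#' @export
classification_report <- function(preds, truths) {
  cc <- confusion_counts(preds, truths)
  tp <- cc["tp"]; fp <- cc["fp"]; fn <- cc["fn"]; tn <- cc["tn"]
  accuracy <- (tp + tn) / sum(cc)
  precision <- if (tp + fp == 0) as.numeric(tp + fn == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) as.numeric(tp + fp == 0) else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = unname(accuracy), precision = unname(precision),
    recall = unname(recall), f1 = unname(f1))
}
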