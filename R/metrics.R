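#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred_mask,gt_mask Binary (0/1) matrices of identical shape.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn` summing to the number of pixels.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop_sym("prediction and ground truth shapes differ")
  assert_binary_mask(pred_mask, "pred_mask")
  assert_binary_mask(gt_mask, "gt_mask")
  p <- as.logical(pred_mask); g <- as.logical(gt_mask)
  structure(list(tp = sum(p & g), tn = sum(!p & !g),
                 fp = sum(p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

sum_counts <- function(counts) {
  structure(list(tp = sum(vapply(counts, `[[`, 0, "tp")),
                 tn = sum(vapply(counts, `[[`, 0, "tn")),
                 fp = sum(vapply(counts, `[[`, 0, "fp")),
                 fn = sum(vapply(counts, `[[`, 0, "fn"))),
            class = "confusion_counts")
}

#' Pixel accuracy: (TP + TN) / (TP + FP + FN + TN)
#' @param c A [confusion_counts()].
#' @return A value in `[0, 1]`.
#' @export
pixel_accuracy <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot == 0) stop_sym("pixel_accuracy undefined for zero pixels")
  (c$tp + c$tn) / tot
}

#' Dice similarity coefficient: 2TP / (FP + 2TP + FN)
#'
#' When both masks are empty (denominator 0) the coefficient is defined as 1
#' by convention: no nodule present, none predicted.
#' @param c A [confusion_counts()].
#' @return A value in `[0, 1]`.
#' @export
dice_coefficient <- function(c) {
  den <- c$fp + 2 * c$tp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Sensitivity (true positive rate): TP / (TP + FN)
#'
#' `NA` when the ground truth has no positive pixels and the prediction does
#' (undefined); 1 when both are empty.
#' @param c A [confusion_counts()].
#' @return A value in `[0, 1]` or `NA`.
#' @export
tpr <- function(c) {
  if (c$tp + c$fn == 0) return(if (c$fp == 0) 1 else NA_real_)
  c$tp / (c$tp + c$fn)
}

#' Specificity (true negative rate): TN / (TN + FP)
#' @param c A [confusion_counts()].
#' @return A value in `[0, 1]` or `NA` when there are no negative pixels.
#' @export
tnr <- function(c) {
  if (c$tn + c$fp == 0) return(if (c$fn == 0) 1 else NA_real_)
  c$tn / (c$tn + c$fp)
}

metrics_from_counts <- function(c) {
  c(pa = pixel_accuracy(c), dsc = dice_coefficient(c),
    tpr = tpr(c), tnr = tnr(c))
}

#' Evaluate a list of predicted masks against references
#'
#' `per_image_mean` computes the four metrics per image and averages them
#' (images where a metric is undefined are excluded from that metric's mean);
#' `pooled` sums the confusion counts over all images first.
#'
#' @param preds,gts Equal-length lists of binary masks with matching shapes.
#' @param aggregation `"per_image_mean"` (default) or `"pooled"`.
#' @return An object of class `seg_metrics`: fields `pa`, `dsc`, `tpr`,
#'   `tnr`, `n_images`, `aggregation`.
#' @export
evaluate_pairs <- function(preds, gts,
                           aggregation = c("per_image_mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (length(preds) == 0L) stop_sym("empty list of predictions")
  if (length(preds) != length(gts))
    stop_sym("preds and gts must have equal length")
  counts <- Map(confusion_counts, preds, gts)
  vals <- if (aggregation == "pooled") {
    metrics_from_counts(sum_counts(counts))
  } else {
    m <- do.call(rbind, lapply(counts, metrics_from_counts))
    colMeans(m, na.rm = TRUE)
  }
  structure(list(pa = unname(vals["pa"]), dsc = unname(vals["dsc"]),
                 tpr = unname(vals["tpr"]), tnr = unname(vals["tnr"]),
                 n_images = length(preds), aggregation = aggregation),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> n=%d (%s)  PA=%.4f DSC=%.4f TPR=%.4f TNR=%.4f\n",
              x$n_images, x$aggregation, x$pa, x$dsc, x$tpr, x$tnr))
  invisible(x)
}

#' Binarize a probability map at a threshold
#' @param probs Numeric array of probabilities.
#' @param threshold Decision threshold, default 0.5.
#' @return A 0/1 array of the same shape.
#' @export
binarize <- function(probs, threshold = 0.5) {
  out <- (probs >= threshold) * 1
  dim(out) <- dim(probs)
  out
}

# Cross-pair results table mirroring the source/target layout of multi-site
# evaluations, with an Average row over the pair rows (not pooled pixels).
metrics_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(source = r$source, target = r$target, pa = r$metrics$pa,
               dsc = r$metrics$dsc, tpr = r$metrics$tpr, tnr = r$metrics$tnr,
               stringsAsFactors = FALSE)))
  if (nrow(df) > 1L) {
    avg <- data.frame(source = "Average", target = "",
                      pa = mean(df$pa), dsc = mean(df$dsc),
                      tpr = mean(df$tpr), tnr = mean(df$tnr),
                      stringsAsFactors = FALSE)
    df <- rbind(df, avg)
  }
  df
}
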