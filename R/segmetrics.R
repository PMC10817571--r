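#' Pixel-wise confusion counts between a predicted and a true mask
#'
#' @param pred,truth binary matrices of identical dimensions.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`; the four always sum to the pixel count.
#' @export
confusion <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    nt_stop("pred and truth differ in shape", "nervetrace_geometry_error")
  }
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- length(pred) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Precision, recall, DICE and IoU from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' DICE = 2TP/(2TP+FP+FN) (the harmonic mean of precision and recall) and
#' IoU = TP/(TP+FP+FN). Degenerate denominators follow the conventions:
#' with no predicted foreground, precision is 1 when the truth is also
#' empty and 0 otherwise (symmetrically for recall); DICE and IoU of two
#' empty masks are 1.
#'
#' @param counts a `confusion_counts` object (or list with tp/fp/fn).
#' @return An object of class `seg_metrics` with fields `precision`,
#'   `recall`, `dice`, `iou`, all in \[0, 1\].
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn) < 0)) nt_stop("counts must be nonnegative", "nervetrace_config_error")
  precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(fn == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else as.numeric(fp == 0)
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  structure(list(precision = precision, recall = recall, dice = dice,
                 iou = iou), class = "seg_metrics")
}

#' Per-image segmentation metrics for a predicted/true mask pair
#' @inheritParams confusion
#' @return A `seg_metrics` object.
#' @export
seg_metrics <- function(pred, truth) {
  metrics_from_counts(confusion(pred, truth))
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  DICE %.3f  IoU %.3f\n",
              x$precision, x$recall, x$dice, x$iou))
  invisible(x)
}

#' Summarise per-image metrics: mean, SD and the IoU distribution
#'
#' Means and sample standard deviations (n - 1 denominator) are taken over
#' images, matching per-image evaluation rather than pixel pooling. The IoU
#' distribution uses ten bins of width 0.1 on \[0, 1\] (the last bin closed
#' at 1); the mode is reported as the left edge of the most populated bin
#' (ties resolve to the lowest bin).
#'
#' @param per_image list of `seg_metrics` objects (or a data frame with
#'   columns precision/recall/dice/iou).
#' @return A list of class `metrics_summary`: `summary` data frame
#'   (metric, mean, sd), `iou_hist` (named bin counts), `iou_mode`,
#'   `iou_min` and `n`.
#' @export
summarize_metrics <- function(per_image) {
  if (is.data.frame(per_image)) {
    df <- per_image
  } else {
    if (!length(per_image)) nt_stop("no per-image metrics", "nervetrace_size_error")
    df <- do.call(rbind, lapply(per_image, function(m)
      data.frame(precision = m$precision, recall = m$recall,
                 dice = m$dice, iou = m$iou)))
  }
  if (!nrow(df)) nt_stop("no per-image metrics", "nervetrace_size_error")
  mets <- c("precision", "recall", "dice", "iou")
  summ <- data.frame(
    metric = mets,
    mean = unname(vapply(mets, function(m) mean(df[[m]]), numeric(1))),
    sd = unname(vapply(mets, function(m)
      if (nrow(df) > 1) stats::sd(df[[m]]) else 0, numeric(1))),
    row.names = NULL)
  bins <- pmin(floor(df$iou * 10), 9) + 1L
  counts <- tabulate(bins, nbins = 10L)
  names(counts) <- sprintf("[%.1f,%.1f%s", seq(0, 0.9, 0.1), seq(0.1, 1, 0.1),
                           c(rep(")", 9), "]"))
  structure(list(summary = summ, iou_hist = counts,
                 iou_mode = (unname(which.max(counts)) - 1L) / 10,
                 iou_min = min(df$iou), n = nrow(df)),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d images (mean +/- SD):\n", x$n))
  with(x$summary, for (i in seq_along(metric)) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", metric[i], mean[i], sd[i]))
  })
  cat(sprintf("  IoU mode bin %.1f, minimum IoU %.3f\n", x$iou_mode, x$iou_min))
  invisible(x)
}
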