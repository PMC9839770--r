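# Segmentation metrics from pixel confusion counts: mean pixel accuracy
# (mean over classes of per-class recall), IoU = TP/(TP+FP+FN) per class, and
# Dice = 2TP/(2TP+FP+FN).  Foreground is the positive class.  When a metric's
# denominator is empty (both masks empty for that class) the score is defined
# as 1: an empty prediction of an empty truth is perfect agreement.

#' Pixel confusion counts between a predicted and a true binary mask
#'
#' @param pred,truth Aligned integer 0/1 matrices; foreground = 1.
#' @return List with non-negative integer fields \code{tp}, \code{fp},
#'   \code{fn}, \code{tn} summing to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_seg_mask(pred); truth <- as_seg_mask(truth)
  stopifnot_aligned(pred, truth, "pred and truth")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Mean pixel accuracy over classes
#'
#' mPA = (1/k) * sum_j n_jj / t_j, where n_jj is the number of pixels
#' correctly classified as class j and t_j the number of ground-truth pixels
#' of class j (per-class recall).  Classes absent from the ground truth are
#' excluded from the mean.
#'
#' @param counts A confusion-count list from \code{\link{confusion_counts}}
#'   (two classes: background and foreground).
#' @return mPA in \[0, 1\].
#' @export
pixel_accuracy_per_class <- function(counts) {
  correct <- c(bg = counts$tn, fg = counts$tp)
  totals <- c(bg = counts$tn + counts$fp, fg = counts$tp + counts$fn)
  present <- totals > 0
  if (!any(present)) stop("no pixels to evaluate", call. = FALSE)
  mean(correct[present] / totals[present])
}

#' Foreground intersection-over-union
#'
#' IoU = TP / (TP + FP + FN) = |X intersect Y| / |X union Y| for the
#' foreground pixel sets X (prediction) and Y (truth); 1 when both are empty.
#'
#' @param counts Confusion counts.
#' @return IoU in \[0, 1\].
#' @export
iou_score <- function(counts) {
  denom <- counts$tp + counts$fp + counts$fn
  if (denom == 0) return(1)
  counts$tp / denom
}

#' Dice similarity score
#'
#' Dice = 2TP / (2TP + FP + FN); 1 when both masks are empty.  Equal to
#' \code{2 IoU / (1 + IoU)} for the same counts.
#'
#' @param counts Confusion counts.
#' @return Dice in \[0, 1\].
#' @export
dice_score <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) return(1)
  2 * counts$tp / denom
}

# IoU of the background class: swap the roles of 0 and 1.
iou_background <- function(counts) {
  denom <- counts$tn + counts$fn + counts$fp
  if (denom == 0) return(1)
  counts$tn / denom
}

metric_row <- function(counts) {
  fg <- iou_score(counts)
  data.frame(mpa = pixel_accuracy_per_class(counts),
             iou_fg = fg,
             iou_bg = iou_background(counts),
             miou = (fg + iou_background(counts)) / 2,
             dice = dice_score(counts))
}

#' Evaluate a set of predicted masks against ground truth
#'
#' Two aggregation modes are computed as requested: \code{micro} pools
#' confusion counts over every pixel of every image before applying the
#' metric formulas; \code{per_image} computes each metric per image and
#' averages.  mIoU is the mean of foreground and background IoU (2-class
#' mIoU); the foreground-only IoU is reported alongside.
#'
#' @param preds,truths Equal-length lists of aligned 0/1 mask matrices.
#' @param mode \code{"micro"} (default) or \code{"per_image"}.
#' @param ids Optional character vector of image identifiers.
#' @return A \code{metric_report}: list with \code{mpa}, \code{miou},
#'   \code{iou_fg}, \code{iou_bg}, \code{dice}, \code{mode}, and a
#'   \code{per_image} data.frame (one row per image).
#' @export
evaluate_dataset <- function(preds, truths, mode = c("micro", "per_image"),
                             ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(preds) == length(truths))
  if (length(preds) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  rows <- vector("list", length(preds))
  pooled <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(preds)) {
    cc <- confusion_counts(preds[[i]], truths[[i]])
    pooled <- Map(`+`, pooled, cc)
    rows[[i]] <- cbind(data.frame(id = ids[i]), metric_row(cc))
  }
  per_image <- do.call(rbind, rows)
  summary <- if (mode == "micro") metric_row(pooled) else
    as.data.frame(lapply(per_image[-1], mean))
  structure(c(as.list(summary),
              list(mode = mode, per_image = per_image,
                   pooled_counts = pooled)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report (%s, %d images)>\n", x$mode, nrow(x$per_image)))
  cat(sprintf("  mPA %.4f | mIoU %.4f (fg %.4f, bg %.4f) | Dice %.4f\n",
              x$mpa, x$miou, x$iou_fg, x$iou_bg, x$dice))
  invisible(x)
}

#' Write a metric report as TSV (per-image rows plus a summary row)
#'
#' @param report A \code{metric_report}.
#' @param path Output TSV path.
#' @export
write_metric_report <- function(report, path) {
  tab <- report$per_image
  summary <- data.frame(id = paste0("<", report$mode, ">"),
                        mpa = report$mpa, iou_fg = report$iou_fg,
                        iou_bg = report$iou_bg, miou = report$miou,
                        dice = report$dice)
  write.table(rbind(tab, summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
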