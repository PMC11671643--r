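# Segmentation and classification metrics: Dice, IoU, precision, recall on
# binary masks; pixel-wise AUC on the raw error map; per-volume aggregation.

.maskValues <- function(x) {
  v <- if (is(x, "BinaryMask")) x@values else x
  if (!is.logical(v)) v <- v > 0.5
  v
}

#' Pixel confusion counts between a predicted and a true mask
#'
#' @param pred Predicted [BinaryMask-class] (or logical matrix).
#' @param truth Ground-truth mask of the same shape.
#' @return Named integer vector `tp`, `fp`, `fn`, `tn`
#'   (summing to the pixel count).
#' @export
confusionCounts <- function(pred, truth) {
  p <- .maskValues(pred); g <- .maskValues(truth)
  .assertSameShape(p, g, "pred and truth")
  c(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
}

#' Segmentation overlap scores
#'
#' Dice `2tp/(2tp+fp+fn)`, IoU `tp/(tp+fp+fn)`, precision `tp/(tp+fp)` and
#' recall `tp/(tp+fn)`. Degenerate conventions: if both masks are empty all
#' four scores are 1 (perfect agreement); an empty prediction against a
#' non-empty truth (or vice versa for the affected ratios) scores 0.
#'
#' @param pred Predicted [BinaryMask-class] (or logical matrix).
#' @param truth Ground-truth mask.
#' @return One-row data.frame: `dice`, `iou`, `precision`, `recall`,
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
segScores <- function(pred, truth) {
  cc <- confusionCounts(pred, truth)
  tp <- cc["tp"]; fp <- cc["fp"]; fn <- cc["fn"]
  if (tp + fp + fn == 0) {
    dice <- iou <- prec <- rec <- 1
  } else {
    dice <- as.numeric(2 * tp / (2 * tp + fp + fn))
    iou <- as.numeric(tp / (tp + fp + fn))
    prec <- if (tp + fp == 0) 0 else as.numeric(tp / (tp + fp))
    rec <- if (tp + fn == 0) 0 else as.numeric(tp / (tp + fn))
  }
  data.frame(dice = dice, iou = iou, precision = prec, recall = rec,
             tp = cc["tp"], fp = cc["fp"], fn = cc["fn"], tn = cc["tn"],
             row.names = NULL)
}

#' Pixel-wise ROC AUC of an anomaly map
#'
#' Treats the per-pixel error values as a ranking of pixels and computes the
#' area under the ROC curve against the ground-truth mask via the
#' Mann-Whitney U statistic (midranks for ties): the probability that a
#' random anomalous pixel scores above a random normal one.
#'
#' @param scores An [AnomalyMap-class] (or numeric matrix).
#' @param truth Ground-truth [BinaryMask-class] (or logical matrix) with
#'   both classes present.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) for single-class truth.
#' @export
pixelAUC <- function(scores, truth) {
  s <- as.vector(.asPixelMatrix(scores))
  g <- as.vector(.maskValues(truth))
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0) {
    warning("pixel AUC is undefined for single-class ground truth", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(s)  # midranks for ties
  (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate per-slice scores into mean and standard deviation
#'
#' @param scores A data.frame of per-slice metric rows (e.g. rbind-ed
#'   [segScores()] output, possibly with an `auc` column), or a list of
#'   such rows.
#' @param metrics Columns to aggregate (defaults to all numeric metric
#'   columns present).
#' @return Data.frame with `metric`, `mean`, `sd` (population standard
#'   deviation, i.e. divisor n).
#' @export
aggregateScores <- function(scores,
                            metrics = c("dice", "iou", "precision",
                                        "recall", "auc")) {
  if (is.list(scores) && !is.data.frame(scores))
    scores <- do.call(rbind, scores)
  if (nrow(scores) == 0L) stop("no scores to aggregate", call. = FALSE)
  metrics <- intersect(metrics, colnames(scores))
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(metric = metrics,
             mean = vapply(metrics, function(m) mean(scores[[m]]), numeric(1)),
             sd = vapply(metrics, function(m) popSd(scores[[m]]), numeric(1)),
             row.names = NULL)
}

#' Equidistant slice indices within an annotated range
#'
#' Picks `n` (default 4) equally spaced slice indices spanning
#' `[lo, hi]` -- the per-volume evaluation convention.
#'
#' @param lo,hi First and last slice index of the anomalous range.
#' @param n Number of slices.
#' @return Integer vector of length `n`.
#' @export
equidistantSlices <- function(lo, hi, n = 4L) {
  if (hi < lo) stop("hi must be >= lo", call. = FALSE)
  as.integer(round(seq(lo, hi, length.out = n)))
}
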