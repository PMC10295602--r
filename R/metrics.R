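#' @include AllClasses.R
NULL

#' Tally pixel confusion counts
#'
#' Counts true/false positives/negatives between a predicted and a ground
#' truth binary mask, restricted to ROI pixels when an ROI is given (pixels
#' outside the field of view carry no information).
#'
#' @param pred,truth binary matrices of identical shape.
#' @param roi optional binary matrix; when present only `roi == 1` pixels
#'   are tallied.
#' @return a [ConfusionCounts-class] object; the four counts sum to the
#'   number of evaluated pixels.
#' @examples
#' cc <- confusionCounts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' computeMetrics(cc)
#' @export
confusionCounts <- function(pred, truth, roi = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth shapes differ")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("pred and truth must be strictly binary")
  if (!is.null(roi)) {
    if (!all(dim(roi) == dim(pred))) stop("roi shape differs")
    keep <- roi == 1
    pred <- pred[keep]
    truth <- truth[keep]
  }
  new("ConfusionCounts",
      tp = sum(pred == 1 & truth == 1),
      fp = sum(pred == 1 & truth == 0),
      fn = sum(pred == 0 & truth == 1),
      tn = sum(pred == 0 & truth == 0))
}

.safe_ratio <- function(num, den) {
  if (den == 0) list(v = 0, undef = TRUE) else list(v = num / den, undef = FALSE)
}

#' Compute the five segmentation statistics
#'
#' From pixel confusion counts:
#' accuracy `(TP+TN)/(TP+FP+FN+TN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 `2*precision*recall/(precision+recall)` (the beta = 1
#' F-measure, equal to the Dice coefficient `2TP/(2TP+FP+FN)`), and IoU
#' `TP/(TP+FP+FN)`. A metric whose denominator is zero is reported as 0 and
#' flagged in the report's `undefined` slot, so batch evaluation stays
#' total.
#'
#' @param counts a [ConfusionCounts-class] object with at least one
#'   evaluated pixel.
#' @return a [MetricsReport-class] object.
#' @export
computeMetrics <- function(counts) {
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("no evaluated pixels (all counts zero)")
  undef <- character(0)
  acc <- (tp + tn) / total
  pr <- .safe_ratio(tp, tp + fp)
  if (pr$undef) undef <- c(undef, "precision")
  rc <- .safe_ratio(tp, tp + fn)
  if (rc$undef) undef <- c(undef, "recall")
  f1 <- .safe_ratio(2 * tp, 2 * tp + fp + fn)   # algebraically 2PR/(P+R)
  if (f1$undef) undef <- c(undef, "f1")
  iou <- .safe_ratio(tp, tp + fp + fn)
  if (iou$undef) undef <- c(undef, "iou")
  new("MetricsReport", accuracy = acc, precision = pr$v, recall = rc$v,
      f1 = f1$v, iou = iou$v, undefined = undef)
}

#' Aggregate metrics over several images
#'
#' `"micro"` pools the confusion counts and computes the statistics once
#' (every pixel weighs equally); `"macro"` averages the per-image
#' statistics (every image weighs equally). The two differ when image sizes
#' or prevalences differ.
#'
#' @param counts_list non-empty list of [ConfusionCounts-class] objects.
#' @param mode `"micro"` (default) or `"macro"`.
#' @return a [MetricsReport-class] object.
#' @export
aggregateMetrics <- function(counts_list, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (length(counts_list) == 0) stop("empty list")
  if (mode == "micro") {
    tot <- new("ConfusionCounts",
               tp = sum(vapply(counts_list, slot, numeric(1), "tp")),
               fp = sum(vapply(counts_list, slot, numeric(1), "fp")),
               fn = sum(vapply(counts_list, slot, numeric(1), "fn")),
               tn = sum(vapply(counts_list, slot, numeric(1), "tn")))
    return(computeMetrics(tot))
  }
  reps <- lapply(counts_list, computeMetrics)
  avg <- function(s) mean(vapply(reps, slot, numeric(1), s))
  new("MetricsReport", accuracy = avg("accuracy"), precision = avg("precision"),
      recall = avg("recall"), f1 = avg("f1"), iou = avg("iou"),
      undefined = unique(unlist(lapply(reps, slot, "undefined"))))
}

#' Convert a metrics report to a one-row data frame
#'
#' @param report a [MetricsReport-class] object.
#' @param counts optional [ConfusionCounts-class] to include the tallies.
#' @param sample_id optional identifier column.
#' @return one-row `data.frame`.
#' @export
metricsAsRow <- function(report, counts = NULL, sample_id = NA_character_) {
  row <- data.frame(sample_id = sample_id,
                    accuracy = report@accuracy, precision = report@precision,
                    recall = report@recall, f1 = report@f1, iou = report@iou,
                    stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    row$TP <- counts@tp; row$FP <- counts@fp
    row$FN <- counts@fn; row$TN <- counts@tn
  }
  row
}
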