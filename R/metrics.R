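#' Logistic sigmoid
#'
#' The output activation of the network: `1 / (1 + exp(-x))`.
#'
#' @param x Numeric vector or array.
#' @return Values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' Pixel-wise binary cross-entropy between a probability map and a binary
#' ground-truth mask: `-sum(y * log(p) + (1 - y) * log(1 - p))`, optionally
#' divided by the number of pixels. Predictions are clipped to
#' `[eps, 1 - eps]` before the logarithms.
#'
#' @param pred Numeric array of probabilities.
#' @param truth Binary array of the same shape.
#' @param reduction `"mean"` or `"sum"`.
#' @param eps Clipping epsilon (default 1e-7).
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, truth, reduction = c("mean", "sum"), eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (!identical(dim2(pred), dim2(truth)))
    stop("invalid argument: pred and truth shapes differ")
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  y <- as.numeric(truth)
  if (!all(y %in% c(0, 1))) stop("invalid argument: truth must be binary")
  total <- -sum(y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "mean") total / length(p) else total
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Threshold a probability map
#'
#' A pixel is foreground iff its probability is greater than or equal to the
#' threshold (boundary inclusive).
#'
#' @param pred Numeric array of probabilities.
#' @param threshold Threshold in (0, 1).
#' @return Integer array of 0/1 with the shape of `pred`.
#' @export
binarize <- function(pred, threshold = 0.5) {
  out <- (pred >= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred Binary predicted mask.
#' @param truth Binary ground-truth mask of the same shape.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim2(pred), dim2(truth)))
    stop("invalid argument: pred and truth shapes differ")
  p <- as.numeric(pred); y <- as.numeric(truth)
  if (!all(p %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("invalid argument: confusion() requires binary masks")
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  tn <- sum(p == 0 & y == 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# Shared degenerate-denominator convention: if the metric's denominator is
# zero, return 1 when prediction and truth are both empty (tp+fp+fn == 0)
# and 0 otherwise. This keeps per-image averaging well defined.
metric_ratio <- function(num, den, c) {
  if (den == 0) return(if (c$tp + c$fp + c$fn == 0) 1 else 0)
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `iou = TP / (TP + FP + FN)`, `dice = 2 TP / (2 TP + FP + FN)`.
#' When both masks are empty every metric is 1; when the denominator is zero
#' but the masks disagree the metric is 0.
#'
#' @param c A [confusion()] result (any list with tp/fp/fn/tn works).
#' @return Fraction in \[0, 1\].
#' @export
recall <- function(c) metric_ratio(c$tp, c$tp + c$fn, c)

#' @rdname recall
#' @export
precision <- function(c) metric_ratio(c$tp, c$tp + c$fp, c)

#' @rdname recall
#' @export
iou <- function(c) metric_ratio(c$tp, c$tp + c$fp + c$fn, c)

#' @rdname recall
#' @export
dice <- function(c) metric_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, c)

#' Evaluate predictions against ground truth masks
#'
#' Thresholds every probability map, tallies pixel confusion counts and
#' reports Dice, IoU, recall and precision, either averaged per image
#' (`"per-image-mean"`, the convention of the segmentation comparison
#' literature) or computed from counts pooled over the whole set
#' (`"global-pooled"`).
#'
#' @param preds List of probability maps (or a single map).
#' @param truths List of binary masks, same length and shapes.
#' @param threshold Binarisation threshold.
#' @param aggregation `"per-image-mean"` or `"global-pooled"`.
#' @return An object of class `metrics_report`: list with `dice`, `iou`,
#'   `recall`, `precision`, pooled `counts`, `aggregation` and `n_images`.
#' @export
evaluate_dataset <- function(preds, truths, threshold = 0.5,
                             aggregation = c("per-image-mean", "global-pooled")) {
  aggregation <- match.arg(aggregation)
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  if (length(preds) != length(truths))
    stop("invalid argument: preds and truths differ in length")
  if (length(preds) == 0) stop("invalid argument: empty evaluation set")
  per <- lapply(seq_along(preds), function(i) {
    confusion(binarize(preds[[i]], threshold), truths[[i]])
  })
  pooled <- structure(list(tp = sum(vapply(per, `[[`, numeric(1), "tp")),
                           fp = sum(vapply(per, `[[`, numeric(1), "fp")),
                           fn = sum(vapply(per, `[[`, numeric(1), "fn")),
                           tn = sum(vapply(per, `[[`, numeric(1), "tn"))),
                      class = "confusion_counts")
  metrics <- if (aggregation == "per-image-mean") {
    list(dice = mean(vapply(per, dice, numeric(1))),
         iou = mean(vapply(per, iou, numeric(1))),
         recall = mean(vapply(per, recall, numeric(1))),
         precision = mean(vapply(per, precision, numeric(1))))
  } else {
    list(dice = dice(pooled), iou = iou(pooled),
         recall = recall(pooled), precision = precision(pooled))
  }
  structure(c(metrics, list(counts = pooled, aggregation = aggregation,
                            n_images = length(preds))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("segmentation metrics (%s, n = %d):\n", x$aggregation, x$n_images))
  cat(sprintf("  Dice %.4f  IoU %.4f  Recall %.4f  Precision %.4f\n",
              x$dice, x$iou, x$recall, x$precision))
  invisible(x)
}

#' Serialise a metrics report to JSON
#'
#' @param x A `metrics_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
metrics_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "metrics_report"))
  obj <- list(dice = x$dice, iou = x$iou, recall = x$recall,
              precision = x$precision, aggregation = x$aggregation,
              n_images = x$n_images, counts = unclass(x$counts))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
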