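#' Pixel-wise accuracy of a predicted mask against ground truth
#'
#' Overall pixel agreement: `100 * #(pred == truth) / #pixels`. This is the
#' method's headline measure; it is sensitive to class imbalance, so
#' [mask_metrics()] also reports IoU, precision, and recall of the
#' vegetation class.
#'
#' @param pred,truth [binary_mask()] objects (or 0/255 matrices) of identical
#'   dimensions.
#' @return Accuracy percentage in `[0, 100]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  pred <- binary_mask(pred); truth <- binary_mask(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("mask dimensions differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(truth), collapse = "x"), call. = FALSE)
  }
  100 * mean(unclass(pred) == unclass(truth))
}

#' Full confusion-derived metrics for a predicted vegetation mask
#'
#' @inheritParams pixel_accuracy
#' @return One-row data frame: `accuracy_pct`, `iou`, `precision`, `recall`,
#'   `n_pixels`. IoU/precision/recall are `NA` when undefined (no vegetation
#'   in the relevant masks).
#' @export
mask_metrics <- function(pred, truth) {
  pred <- binary_mask(pred); truth <- binary_mask(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  p <- unclass(pred) == 255L
  t <- unclass(truth) == 255L
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  data.frame(
    accuracy_pct = 100 * mean(p == t),
    iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    n_pixels = length(p)
  )
}

#' Summarize accuracy records per method
#'
#' @param records Data frame with at least columns `method` and
#'   `accuracy_pct` (one row per image x method, as produced by the
#'   evaluation pipeline).
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return Data frame with one row per method: `method`, `n`, `mean_pct`,
#'   `sd_pct` (`NA` for a single sample record, 0 for a single population
#'   record).
#' @export
summarize_accuracy <- function(records, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("method", "accuracy_pct") %in% names(records)))
  out <- do.call(rbind, lapply(split(records, records$method), function(d) {
    n <- nrow(d)
    s <- if (n == 1L) {
      if (sd_type == "population") 0 else NA_real_
    } else {
      s0 <- stats::sd(d$accuracy_pct)
      if (sd_type == "population") s0 * sqrt((n - 1) / n) else s0
    }
    data.frame(method = d$method[1], n = n,
               mean_pct = mean(d$accuracy_pct), sd_pct = s)
  }))
  rownames(out) <- NULL
  out
}
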