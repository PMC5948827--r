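#' Segment vegetation in an RGB image by hue-histogram threshold detection
#'
#' Runs the full four-stage method: RGB to HSV conversion, hue-histogram
#' construction and small-presence filtering, two-term Gaussian fitting and
#' five-candidate threshold detection, and binarization of the hue plane at
#' the combined threshold.
#'
#' @param img An [rgb_image()] (or `H x W x 3` array of 8-bit values).
#' @param config Optional [hueseg_config()].
#' @return A list: `mask` ([binary_mask()]), `report`
#'   (`threshold_report`), `fit` (`gaussian_fit`), `histogram` (the filtered
#'   `hue_histogram`), `hsv` (`hsv_image`).
#' @examples
#' scene <- generate_field(field_spec(height = 64, width = 64, seed = 7))
#' res <- segment_hue(scene$image)
#' res$report$final_threshold
#' pixel_accuracy(res$mask, scene$truth)
#' @export
segment_hue <- function(img, config = NULL) {
  config <- as_hueseg_config(config)
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  hsv <- rgb_to_hsv_image(img)
  hist0 <- build_hue_histogram(hsv)
  histf <- filter_hue_histogram(hist0, config)
  fit <- fit_hue_gaussians(histf, config)
  report <- detect_thresholds(fit, histf, config)
  mask <- binarize_hue(hsv, report, config)
  list(mask = mask, report = report, fit = fit, histogram = histf, hsv = hsv)
}

#' Segment an image file and write mask + report
#'
#' @param path Input image path (PNG/TIFF/JPEG).
#' @param out_dir Output directory.
#' @param method `"proposed"` (hue-histogram thresholds) or one of
#'   [index_names()] or `"hue"` (index/hue + Otsu baseline).
#' @param config Optional [hueseg_config()].
#' @return Invisibly, a list with the mask path, report path (proposed
#'   method only), and the threshold used.
#' @export
segment_file <- function(path, out_dir, method = "proposed", config = NULL) {
  config <- as_hueseg_config(config)
  img <- load_rgb(path, config)
  stem <- tools::file_path_sans_ext(basename(path))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
  if (method == "proposed") {
    res <- segment_hue(img, config)
    save_mask(res$mask, mask_path)
    report_path <- file.path(out_dir, paste0(stem, "_report.json"))
    write_threshold_report(res$report, report_path)
    invisible(list(mask = mask_path, report = report_path,
                   threshold = res$report$final_threshold))
  } else {
    res <- baseline_segment(img, method, config)
    save_mask(res$mask, mask_path)
    invisible(list(mask = mask_path, report = NULL,
                   threshold = res$threshold))
  }
}
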