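#' Apply the final threshold to a hue image
#'
#' Produces the vegetation binary mask (255 = vegetation). The comparison at
#' the threshold keeps the threshold bin with the dominant class: when soil
#' dominates (search toward increasing hue) vegetation is
#' `final_threshold < hue <= veg_hue_max`; when vegetation dominates (search
#' toward decreasing hue) vegetation is `final_threshold <= hue <=
#' veg_hue_max`. Hues above `veg_hue_max` (180 degrees by default, the cyan
#' end of green) are never vegetation.
#'
#' @param hue `H x W` matrix of hue degrees, or an `hsv_image`.
#' @param report A `threshold_report` with a `final_threshold`, or a single
#'   numeric threshold (then `direction` applies).
#' @param config Optional [hueseg_config()] (`veg_hue_max`).
#' @param direction Search direction used only when `report` is a bare
#'   number; default `"increasing_hue"`.
#' @return A [binary_mask()].
#' @export
binarize_hue <- function(hue, report, config = NULL,
                         direction = "increasing_hue") {
  config <- as_hueseg_config(config)
  if (inherits(hue, "hsv_image")) hue <- hue$h
  if (inherits(report, "threshold_report")) {
    thr <- report$final_threshold
    direction <- report$dominant$direction
  } else {
    thr <- report
  }
  if (is.null(thr) || is.na(thr)) {
    stop("no final threshold available for binarization", call. = FALSE)
  }
  veg <- if (direction == "increasing_hue") {
    hue > thr & hue <= config$veg_hue_max
  } else {
    hue >= thr & hue <= config$veg_hue_max
  }
  binary_mask(matrix(ifelse(veg, 255L, 0L), nrow(hue), ncol(hue)))
}
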