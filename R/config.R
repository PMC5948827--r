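#' Default configuration for the hue-threshold segmentation pipeline
#'
#' Collects every tunable of the method in one list so that a whole run is
#' reproducible from (image, config, seed). Values not overridden keep the
#' defaults below.
#'
#' @param ... Named overrides of individual fields.
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{filter_fraction (1e-5)}{Histogram small-presence cutoff: a 1-degree
#'     hue bin is dropped when its pixel count is strictly below
#'     `filter_fraction * total_pixels` (0.001\% of the image).}
#'   \item{veg_boundary (60)}{Hue (degrees) separating non-vegetation from
#'     vegetation when classifying the dominant peak; the boundary value
#'     itself counts as vegetation (green runs from yellow at 60 degrees to
#'     cyan at 180).}
#'   \item{veg_hue_max (180)}{Upper hue cap of the vegetation class during
#'     binarization; hues above it (magenta/red side) are never vegetation.}
#'   \item{sigma_multiples (c(3, 2, 1))}{Confidence-interval multiples tried
#'     for the Gaussian-border threshold, highest first; the largest multiple
#'     `k` with `k * sigma < S2` wins.}
#'   \item{stop_bounds (c(30, 70))}{Admissible hue interval (degrees,
#'     inclusive) for local-minimum stops of the three histogram-valley
#'     threshold rules; stops outside it are discarded before averaging.}
#'   \item{bounds_all_candidates (FALSE)}{Extend the 30-70 degree filter to the
#'     two Gaussian-curve thresholds as well.}
#'   \item{s2_mode ("histogram")}{How the far end of the dominant distribution
#'     is located when computing the rejection distance S2: `"histogram"`
#'     (last surviving histogram bin opposite the search direction) or
#'     `"fit3sigma"` (dominant centroid minus/plus 3 sigma).}
#'   \item{n_restarts (5)}{Jittered Levenberg-Marquardt restarts for the
#'     histogram Gaussian fit.}
#'   \item{fit_seed (42)}{Seed for the restart jitter (local RNG scope).}
#'   \item{amp_ratio_min (0.05)}{Second fitted component is discarded when its
#'     amplitude is below this fraction of the dominant amplitude.}
#'   \item{max_width (120)}{Second component discarded when its width
#'     parameter `c` exceeds this (degrees).}
#'   \item{min_separation (20)}{Two fitted centroids closer than this
#'     (degrees) are merged into a single peak.}
#'   \item{gauss_half_exponent (FALSE)}{If `TRUE`, fit
#'     `a * exp(-((x - b)/c)^2 / 2)` instead of the default literal form
#'     `a * exp(-((x - b)/c)^2)` (in which `c = sqrt(2) * sigma`).}
#'   \item{index_convention ("chromatic")}{Channel scale for color indices:
#'     `"chromatic"` (r = R/(R+G+B), ...) or `"raw"` (8-bit values). CIVE
#'     always uses raw channels (its additive constant presumes them).}
#'   \item{exr_coef (1.3)}{Red coefficient of the excess-red index.}
#'   \item{index_polarity}{Named character vector giving, per index, which
#'     side of the Otsu cut is vegetation (`"high"` or `"low"`).}
#'   \item{fallback_otsu (FALSE)}{When no candidate threshold survives, fall
#'     back to Otsu on the hue image instead of failing.}
#'   \item{alpha_strip (TRUE)}{Silently drop the alpha channel of RGBA input
#'     images; if `FALSE`, RGBA input is an error.}
#' }
#'
#' @return A named list with class `"hueseg_config"`.
#' @examples
#' cfg <- hueseg_config(stop_bounds = c(20, 80))
#' cfg$stop_bounds
#' @export
hueseg_config <- function(...) {
  cfg <- list(
    filter_fraction = 1e-5,
    veg_boundary = 60,
    veg_hue_max = 180,
    sigma_multiples = c(3, 2, 1),
    stop_bounds = c(30, 70),
    bounds_all_candidates = FALSE,
    s2_mode = "histogram",
    n_restarts = 5L,
    fit_seed = 42L,
    amp_ratio_min = 0.05,
    max_width = 120,
    min_separation = 20,
    gauss_half_exponent = FALSE,
    index_convention = "chromatic",
    exr_coef = 1.3,
    index_polarity = c(
      NDI = "high", ExG = "high", ExR = "low", ExGR = "high", CIVE = "low",
      COM1 = "low", COM2 = "low", NGRDI = "high", VEG = "high", hue = "high"
    ),
    fallback_otsu = FALSE,
    alpha_strip = TRUE
  )
  over <- list(...)
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(nm == "")) {
      stop("all config overrides must be named", call. = FALSE)
    }
    bad <- setdiff(nm, names(cfg))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[nm] <- over
  }
  structure(cfg, class = "hueseg_config")
}

# Accept either a ready config or NULL (-> defaults) in user-facing entry
# points.
as_hueseg_config <- function(config) {
  if (is.null(config)) return(hueseg_config())
  if (inherits(config, "hueseg_config")) return(config)
  if (is.list(config)) return(do.call(hueseg_config, config))
  stop("`config` must be NULL, a hueseg_config, or a named list",
       call. = FALSE)
}
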