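#' @title Synthetic crop-field scenes with exact ground truth
#' @name synthetic_fields
#' @description Generates seeded agricultural scenes with the hue structure
#'   the segmentation method assumes: soil hues clustered below 60 degrees,
#'   vegetation hues in the green band (60-180 degrees), a controllable
#'   vegetation area fraction (sparse early growth through dominant canopy),
#'   and an optional horizontal illumination gradient that perturbs
#'   saturation/value at fixed hue. The ground-truth mask is recorded from
#'   the vegetation support before rendering, so it is exact by construction.
NULL

#' Specify a synthetic field scene
#'
#' Defaults emulate a mid-season row crop: soil hue `N(40, 8)` degrees,
#' vegetation hue `N(110, 12)` degrees, saturation in `[0.3, 0.9]`, value in
#' `[0.3, 0.95]`.
#'
#' @param height,width Image size in pixels.
#' @param veg_fraction Target vegetation area fraction in `[0, 1]`.
#' @param soil_hue_mean,soil_hue_sd Soil hue distribution (degrees).
#' @param veg_hue_mean,veg_hue_sd Vegetation hue distribution (degrees).
#' @param sat_range,val_range Per-class uniform S/V sampling intervals,
#'   within `[0, 1]`.
#' @param layout `"rows"` (parallel crop rows), `"patches"` (blob canopies),
#'   or `"scattered"` (individual small plants).
#' @param row_spacing_px Row period in pixels (rows layout).
#' @param illumination_gradient Amplitude in `[0, 1]` of a horizontal
#'   brightness ramp multiplying S and V (hue untouched).
#' @param seed Integer RNG seed; generation is bit-reproducible.
#' @param allow_class_violation Permit hue means on the wrong side of the
#'   60-degree class boundary (stress tests such as the irrigated-soil
#'   preset).
#' @return A `field_spec` list.
#' @export
field_spec <- function(height = 256L, width = 256L, veg_fraction = 0.3,
                       soil_hue_mean = 40, soil_hue_sd = 8,
                       veg_hue_mean = 110, veg_hue_sd = 12,
                       sat_range = c(0.3, 0.9), val_range = c(0.3, 0.95),
                       layout = c("rows", "patches", "scattered"),
                       row_spacing_px = 32L, illumination_gradient = 0,
                       seed = 1L, allow_class_violation = FALSE) {
  layout <- match.arg(layout)
  if (veg_fraction < 0 || veg_fraction > 1) {
    stop("veg_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!allow_class_violation &&
      (veg_hue_mean < 60 || soil_hue_mean >= 60)) {
    stop("class-inconsistent hue means (veg < 60 or soil >= 60); ",
         "set allow_class_violation = TRUE to override", call. = FALSE)
  }
  if (height < 1 || width < 1) stop("image must be at least 1 x 1",
                                    call. = FALSE)
  if (layout == "rows" && veg_fraction > 0 && row_spacing_px > width) {
    stop("infeasible spec: row spacing exceeds image width", call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         veg_fraction = veg_fraction,
         soil_hue_mean = soil_hue_mean, soil_hue_sd = soil_hue_sd,
         veg_hue_mean = veg_hue_mean, veg_hue_sd = veg_hue_sd,
         sat_range = sat_range, val_range = val_range, layout = layout,
         row_spacing_px = as.integer(row_spacing_px),
         illumination_gradient = illumination_gradient,
         seed = as.integer(seed)),
    class = "field_spec"
  )
}

#' Irrigated-field stress preset
#'
#' Wet organic soil photographs darker and greener; this preset pushes the
#' soil hue distribution up toward the class boundary (mean 65 degrees),
#' reproducing the regime where hue-based separation degrades.
#'
#' @param ... Overrides passed to [field_spec()].
#' @return A `field_spec`.
#' @export
irrigated_field_spec <- function(...) {
  args <- list(...)
  defaults <- list(soil_hue_mean = 65, soil_hue_sd = 10,
                   allow_class_violation = TRUE)
  do.call(field_spec, utils::modifyList(defaults, args))
}

# Vegetation support (logical H x W) per layout, then exact correction to
# round(veg_fraction * npix) pixels by seeded uniform flips. The correction
# is what makes the ground-truth fraction exact regardless of layout
# rounding.
veg_support <- function(spec) {
  H <- spec$height; W <- spec$width
  npix <- H * W
  target <- round(spec$veg_fraction * npix)
  supp <- matrix(FALSE, H, W)
  if (target > 0) {
    if (spec$layout == "rows") {
      per <- spec$row_spacing_px
      won <- spec$veg_fraction * per
      colpos <- (seq_len(W) - 1L) %% per
      veg_col <- colpos < won
      supp[, veg_col] <- TRUE
    } else if (spec$layout == "patches") {
      rmax <- max(3, round(min(H, W) / 8))
      guard <- 0L
      while (sum(supp) < target && guard < 10000L) {
        guard <- guard + 1L
        cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
        rad <- stats::runif(1, 3, rmax)
        xs <- pmax(1, floor(cx - rad)):pmin(W, ceiling(cx + rad))
        ys <- pmax(1, floor(cy - rad)):pmin(H, ceiling(cy + rad))
        d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
        supp[ys, xs] <- supp[ys, xs] | (d2 <= rad^2)
      }
    } else {  # scattered plants: many small disks
      guard <- 0L
      while (sum(supp) < target && guard < 200000L) {
        guard <- guard + 1L
        cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
        rad <- stats::runif(1, 1, 3)
        xs <- pmax(1, floor(cx - rad)):pmin(W, ceiling(cx + rad))
        ys <- pmax(1, floor(cy - rad)):pmin(H, ceiling(cy + rad))
        d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
        supp[ys, xs] <- supp[ys, xs] | (d2 <= rad^2)
      }
    }
  }
  # exact correction
  cur <- sum(supp)
  if (cur > target) {
    on <- which(supp)
    off_idx <- sample(on, cur - target)
    supp[off_idx] <- FALSE
  } else if (cur < target) {
    off <- which(!supp)
    on_idx <- sample(off, target - cur)
    supp[on_idx] <- TRUE
  }
  supp
}

#' Generate a synthetic field scene
#'
#' Draws the vegetation support from the layout, samples per-pixel hue from
#' the pixel's class distribution (clipped to `[0, 360)`), saturation and
#' value uniformly from the class ranges, applies the horizontal
#' illumination ramp to S and V, and renders to 8-bit RGB. Identical specs
#' (including seed) regenerate bit-identical scenes.
#'
#' @param spec A [field_spec()].
#' @return A `synthetic_scene` list: `image` ([rgb_image()]), `truth`
#'   ([binary_mask()]), `spec`.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  withr::with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    supp <- veg_support(spec)
    n <- H * W
    hmat <- matrix(0, H, W); smat <- hmat; vmat <- hmat
    iv <- which(supp); is_ <- which(!supp)
    clip_hue <- function(z) pmin(pmax(z, 0), 359.999)
    if (length(iv)) {
      hmat[iv] <- clip_hue(stats::rnorm(length(iv), spec$veg_hue_mean,
                                        spec$veg_hue_sd))
      smat[iv] <- stats::runif(length(iv), spec$sat_range[1],
                               spec$sat_range[2])
      vmat[iv] <- stats::runif(length(iv), spec$val_range[1],
                               spec$val_range[2])
    }
    if (length(is_)) {
      hmat[is_] <- clip_hue(stats::rnorm(length(is_), spec$soil_hue_mean,
                                         spec$soil_hue_sd))
      smat[is_] <- stats::runif(length(is_), spec$sat_range[1],
                                spec$sat_range[2])
      vmat[is_] <- stats::runif(length(is_), spec$val_range[1],
                                spec$val_range[2])
    }
    if (spec$illumination_gradient > 0) {
      ramp <- if (W > 1) (seq_len(W) - 1) / (W - 1) - 0.5 else 0
      g <- 1 + spec$illumination_gradient * ramp
      gm <- matrix(g, H, W, byrow = TRUE)
      smat <- pmin(pmax(smat * gm, 0), 1)
      vmat <- pmin(pmax(vmat * gm, 0), 1)
    }
    img <- hsv_to_rgb_image(list(h = hmat, s = smat, v = vmat))
    truth <- binary_mask(matrix(ifelse(supp, 255L, 0L), H, W))
    structure(list(image = img, truth = truth, spec = spec),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d x %d, layout %s, veg fraction %.3f>\n",
              x$spec$height, x$spec$width, x$spec$layout,
              mean(unclass(x$truth) == 255L)))
  invisible(x)
}

#' Generate a growth series of scenes
#'
#' One scene per vegetation fraction, with per-scene seeds derived from the
#' base spec's seed (`seed + index`) and every other field shared -- the
#' synthetic analogue of imaging the same field across growth stages.
#'
#' @param base A [field_spec()] whose `veg_fraction` is overridden.
#' @param fractions Numeric vector of vegetation fractions in `[0, 1]`.
#' @return List of `synthetic_scene` objects (empty for empty `fractions`).
#' @export
growth_series <- function(base, fractions) {
  stopifnot(inherits(base, "field_spec"))
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  lapply(seq_along(fractions), function(i) {
    sp <- base
    sp$veg_fraction <- fractions[i]
    sp$seed <- base$seed + i
    generate_field(sp)
  })
}

#' Write a scene to disk as paired image/mask/spec files
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem; produces `<stem>.png`, `<stem>_mask.png`,
#'   `<stem>_spec.json`.
#' @return Invisibly, the three paths.
#' @export
save_scene <- function(scene, dir, stem) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_img <- file.path(dir, paste0(stem, ".png"))
  p_mask <- file.path(dir, paste0(stem, "_mask.png"))
  p_spec <- file.path(dir, paste0(stem, "_spec.json"))
  png::writePNG(unclass(scene$image) / 255, target = p_img)
  save_mask(scene$truth, p_mask)
  jsonlite::write_json(unclass(scene$spec), p_spec, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(image = p_img, mask = p_mask, spec = p_spec))
}
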