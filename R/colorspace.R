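#' @title Raster input/output and the RGB to HSV transform
#' @name colorspace
#' @description Images are held as plain arrays: an RGB image is an
#'   `H x W x 3` integer array of 8-bit channel values, an HSV image a list of
#'   three `H x W` matrices (`h` in degrees `[0, 360)`, `s` and `v` in
#'   `[0, 1]`), and a binary vegetation mask an `H x W` matrix over
#'   `{0, 255}` with 255 = vegetation.
NULL

#' Construct an RGB image object from an array of 8-bit channel values
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 255]`.
#' @return An integer `H x W x 3` array with class `"rgb_image"`.
#' @export
rgb_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) stop("image must be at least 1 x 1", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  px <- array(as.integer(round(pixels)), dim = d)
  structure(px, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, 8-bit>\n", d[1], d[2]))
  invisible(x)
}

#' Load an RGB raster image
#'
#' Reads an 8-bit PNG, TIFF, or JPEG file into an [rgb_image()]. 16-bit input
#' is rescaled to 8 bits (divide by 257, round). An alpha channel is stripped
#' when `config$alpha_strip` is `TRUE` (the default) and is an error
#' otherwise; single-channel (grayscale) input is always an error because the
#' method needs color.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @param config Optional [hueseg_config()].
#' @return An [rgb_image()].
#' @export
load_rgb <- function(path, config = NULL) {
  config <- as_hueseg_config(config)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) {
    stop("single-channel (grayscale) image; an RGB image is required: ",
         path, call. = FALSE)
  }
  nch <- dim(raw)[3]
  if (nch == 4L) {
    if (!config$alpha_strip) {
      stop("RGBA input and alpha stripping disabled: ", path, call. = FALSE)
    }
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (nch != 3L) {
    stop("unsupported channel count (", nch, "): ", path, call. = FALSE)
  }
  # readPNG/readTIFF/readJPEG return [0,1] doubles; for 8-bit sources
  # value*255 is exact, for 16-bit sources this is the divide-by-257 rescale.
  rgb_image(round(raw * 255))
}

#' Write a binary vegetation mask as a single-channel PNG
#'
#' Vegetation pixels (255) are written white, background (0) black; the file
#' round-trips losslessly through [load_mask()].
#'
#' @param mask `H x W` matrix over `{0, 255}` (class `"binary_mask"`
#'   accepted).
#' @param path Destination path (`.png`).
#' @export
save_mask <- function(mask, path) {
  mask <- binary_mask(mask)
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  png::writePNG(unclass(mask) / 255, target = path)
  invisible(NULL)
}

#' Read a binary mask written by [save_mask()]
#'
#' @param path Path to a single-channel 0/255 PNG.
#' @return A `binary_mask` matrix.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  vals <- round(raw * 255)
  if (!all(vals %in% c(0, 255))) {
    stop("not a binary 0/255 mask: ", path, call. = FALSE)
  }
  binary_mask(vals)
}

#' Construct a binary vegetation mask
#'
#' @param pixels `H x W` matrix with values in `{0, 255}` (255 = vegetation).
#' @return The matrix with class `"binary_mask"`.
#' @export
binary_mask <- function(pixels) {
  if (inherits(pixels, "binary_mask")) return(pixels)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (!all(pixels %in% c(0, 255))) {
    stop("mask values must all be 0 or 255", call. = FALSE)
  }
  structure(matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %.1f%% vegetation>\n",
              nrow(x), ncol(x), 100 * mean(x == 255L)))
  invisible(x)
}

#' Convert an RGB image to HSV
#'
#' Per-pixel hexcone transform: with normalized channels `R' = R/255` (and
#' likewise `G'`, `B'`), `M = max(R', G', B')`, `m = min(...)`, chroma
#' `C = M - m`, hue is `60 * (((G' - B')/C) mod 6)` when the maximum channel
#' is red, `60 * ((B' - R')/C + 2)` when green, `60 * ((R' - G')/C + 4)` when
#' blue, and 0 when `C = 0` (achromatic pixels therefore land at hue 0, on the
#' non-vegetation side). Saturation is `C/M` (0 when `M = 0`) and value is
#' `M`. Hue is returned in degrees `[0, 360)`, so it is invariant under
#' uniform brightness scaling of the three channels -- the property the
#' method relies on for illumination robustness.
#'
#' @param img An [rgb_image()].
#' @return A list with class `"hsv_image"`: matrices `h` (degrees), `s`, `v`.
#' @examples
#' px <- array(c(0, 255, 0), dim = c(1, 1, 3))
#' rgb_to_hsv_image(rgb_image(px))$h  # pure green -> 120 degrees
#' @export
rgb_to_hsv_image <- function(img) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  d <- dim(img)
  ch <- function(k) matrix(unclass(img)[, , k], d[1], d[2])
  rp <- ch(1) / 255
  gp <- ch(2) / 255
  bp <- ch(3) / 255
  M <- pmax(rp, gp, bp)
  m <- pmin(rp, gp, bp)
  C <- M - m
  h <- matrix(0, d[1], d[2])
  chrom <- C > 0
  # branch order fixes ties: red, then green, then blue as the max channel
  iR <- chrom & (M == rp)
  iG <- chrom & (M == gp) & !iR
  iB <- chrom & (M == bp) & !iR & !iG
  h[iR] <- 60 * (((gp[iR] - bp[iR]) / C[iR]) %% 6)
  h[iG] <- 60 * ((bp[iG] - rp[iG]) / C[iG] + 2)
  h[iB] <- 60 * ((rp[iB] - gp[iB]) / C[iB] + 4)
  h[h >= 360] <- 0  # guard the closed upper boundary
  s <- matrix(ifelse(M > 0, C / M, 0), d[1], d[2])
  structure(list(h = h, s = s, v = matrix(M, d[1], d[2])),
            class = "hsv_image")
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("<hsv_image %d x %d, hue range [%.1f, %.1f] deg>\n",
              nrow(x$h), ncol(x$h), min(x$h), max(x$h)))
  invisible(x)
}

#' Convert an HSV image back to an 8-bit RGB image
#'
#' Exact inverse of the hexcone transform up to 8-bit rounding; used by the
#' synthetic field generator to render sampled HSV pixels.
#'
#' @param hsv An `hsv_image` (or list with matrices `h`, `s`, `v`).
#' @return An [rgb_image()].
#' @export
hsv_to_rgb_image <- function(hsv) {
  h <- as.matrix(hsv$h)
  s <- matrix(hsv$s, nrow(h), ncol(h))
  v <- matrix(hsv$v, nrow(h), ncol(h))
  C <- v * s
  hp <- h / 60
  X <- C * (1 - abs(hp %% 2 - 1))
  z <- matrix(0, nrow(h), ncol(h))
  r1 <- z; g1 <- z; b1 <- z
  sect <- floor(hp) %% 6
  idx <- function(k) sect == k
  r1[idx(0)] <- C[idx(0)]; g1[idx(0)] <- X[idx(0)]
  r1[idx(1)] <- X[idx(1)]; g1[idx(1)] <- C[idx(1)]
  g1[idx(2)] <- C[idx(2)]; b1[idx(2)] <- X[idx(2)]
  g1[idx(3)] <- X[idx(3)]; b1[idx(3)] <- C[idx(3)]
  r1[idx(4)] <- X[idx(4)]; b1[idx(4)] <- C[idx(4)]
  r1[idx(5)] <- C[idx(5)]; b1[idx(5)] <- X[idx(5)]
  mm <- v - C
  out <- array(0, dim = c(nrow(h), ncol(h), 3))
  out[, , 1] <- r1 + mm
  out[, , 2] <- g1 + mm
  out[, , 3] <- b1 + mm
  rgb_image(round(out * 255))
}
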