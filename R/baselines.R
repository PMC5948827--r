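#' @title Color-index baselines and Otsu threshold detection
#' @name baselines
#' @description The classical comparison pipeline: a per-pixel color index
#'   turns the RGB image into a grayscale in which vegetation and soil score
#'   differently, and Otsu's criterion picks the cut. Index formulas:
#'   `NDI = 128 * ((g - r)/(g + r) + 1)`, `ExG = 2g - r - b`,
#'   `ExR = 1.3 r - g`, `CIVE = 0.441 R - 0.811 G + 0.385 B + 18.78745`
#'   (raw 8-bit channels), `ExGR = ExG - ExR`,
#'   `COM1 = ExG + CIVE + ExGR + VEG`,
#'   `COM2 = 0.36 ExG + 0.47 CIVE + 0.17 VEG`, `NGRDI = (g - r)/(g + r)`,
#'   `VEG = g / (r^0.667 * b^0.333)`. Lower-case `r, g, b` are chromatic
#'   coordinates (`r = R/(R+G+B)`, ...) under the default convention.
NULL

#' Names of the available color indices
#' @return Character vector.
#' @export
index_names <- function() {
  c("NDI", "ExG", "ExR", "ExGR", "CIVE", "COM1", "COM2", "NGRDI", "VEG")
}

#' Compute a color-index grayscale image
#'
#' @param img An [rgb_image()].
#' @param name One of [index_names()].
#' @param config Optional [hueseg_config()] (`index_convention`, `exr_coef`).
#' @return An `index_image`: list with `values` (`H x W` numeric matrix, all
#'   finite) and `index_name`.
#' @export
compute_index <- function(img, name, config = NULL) {
  config <- as_hueseg_config(config)
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  if (!name %in% index_names()) {
    stop("unknown color index: ", name, call. = FALSE)
  }
  d <- dim(img)
  ch <- function(k) matrix(as.numeric(unclass(img)[, , k]), d[1], d[2])
  R <- ch(1); G <- ch(2); B <- ch(3)
  if (config$index_convention == "chromatic") {
    tot <- R + G + B
    # black pixels (sum 0) get the achromatic point r = g = b = 1/3
    tot[tot == 0] <- 3
    r <- R / tot; g <- G / tot; b <- B / tot
    r[R + G + B == 0] <- 1 / 3
    g[R + G + B == 0] <- 1 / 3
    b[R + G + B == 0] <- 1 / 3
  } else {
    r <- R; g <- G; b <- B
  }
  exg <- function() 2 * g - r - b
  exr <- function() config$exr_coef * r - g
  cive <- function() 0.441 * R - 0.811 * G + 0.385 * B + 18.78745
  veg <- function() {
    eps <- 1e-8
    g / ((r + eps)^0.667 * (b + eps)^0.333)
  }
  vals <- switch(name,
    NDI = {
      den <- g + r
      out <- matrix(128, nrow(g), ncol(g))  # 0/0 -> midpoint
      ok <- den > 0
      out[ok] <- 128 * ((g[ok] - r[ok]) / den[ok] + 1)
      out
    },
    ExG = exg(),
    ExR = exr(),
    ExGR = exg() - exr(),
    CIVE = cive(),
    COM1 = exg() + cive() + (exg() - exr()) + veg(),
    COM2 = 0.36 * exg() + 0.47 * cive() + 0.17 * veg(),
    NGRDI = {
      den <- g + r
      out <- matrix(0, nrow(g), ncol(g))  # 0/0 -> symmetric midpoint 0
      ok <- den > 0
      out[ok] <- (g[ok] - r[ok]) / den[ok]
      out
    },
    VEG = veg()
  )
  stopifnot(all(is.finite(vals)))
  structure(list(values = vals, index_name = name), class = "index_image")
}

#' @export
print.index_image <- function(x, ...) {
  cat(sprintf("<index_image %s, %d x %d, range [%.3f, %.3f]>\n",
              x$index_name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write an index image as 32-bit float TIFF
#' @param idx An `index_image`.
#' @param path Destination `.tif` path.
#' @export
save_index_tiff <- function(idx, path) {
  stopifnot(inherits(idx, "index_image"))
  rng <- range(idx$values)
  # TIFF writer wants [0,1]; store normalized values, range in description
  norm <- if (diff(rng) > 0) (idx$values - rng[1]) / diff(rng) else
    idx$values * 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(rng)
}

#' Otsu threshold of a grayscale image
#'
#' Quantizes the finite-valued image into `levels` equal-width bins over
#' `range` (the data range by default), then picks the cut maximizing the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2` over all splits; ties go
#' to the lowest level. The returned threshold is the bin boundary between
#' the two classes, on the original value scale, so binarization is
#' `value > threshold` for the high class.
#'
#' @param gray Numeric matrix/vector, an `index_image`, or an `hsv_image`
#'   (its hue plane is used with `levels = 360`, `range = c(0, 360)`).
#' @param levels Number of quantization levels (default 256).
#' @param range Length-2 numeric; quantization span. Default: data range.
#' @return Threshold on the input scale.
#' @export
otsu_threshold <- function(gray, levels = 256L, range = NULL) {
  if (inherits(gray, "hsv_image")) {
    if (is.null(range)) range <- c(0, 360)
    levels <- 360L
    gray <- gray$h
  }
  if (inherits(gray, "index_image")) gray <- gray$values
  x <- as.numeric(gray)
  stopifnot(all(is.finite(x)))
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo || length(unique(x)) < 2L) {
    stop("degenerate image: constant values, Otsu threshold undefined",
         call. = FALSE)
  }
  step <- (hi - lo) / levels
  lev <- pmin(levels - 1L, floor((x - lo) / step))  # level index 0..L-1
  cnt <- tabulate(lev + 1L, nbins = levels)
  p <- cnt / sum(cnt)
  mids <- lo + (seq_len(levels) - 0.5) * step
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  # split after level t (1-based index t into cumulatives), t = 1..L-1
  t_idx <- seq_len(levels - 1L)
  w0t <- w0[t_idx]; w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  sb <- rep(-Inf, levels - 1L)
  sb[valid] <- (mu_t * w0t[valid] - mu0[t_idx][valid])^2 /
    (w0t[valid] * w1t[valid])
  t_best <- which.max(sb)  # which.max returns the first (lowest) maximizer
  lo + t_best * step       # boundary between level t_best-1 and t_best (0-based)
}

#' Segment an image with a color-index (or hue) + Otsu baseline
#'
#' Computes the named index (or the hue plane), finds its Otsu threshold,
#' and binarizes with vegetation on the index's bright side -- or dark side
#' for indices where soil scores high (`ExR`, `CIVE`, and the CIVE-dominated
#' combined indices, per `config$index_polarity`).
#'
#' @param img An [rgb_image()].
#' @param name One of [index_names()] or `"hue"`.
#' @param config Optional [hueseg_config()].
#' @return List: `mask` ([binary_mask()]), `threshold`, `index_name`.
#' @export
baseline_segment <- function(img, name, config = NULL) {
  config <- as_hueseg_config(config)
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  if (name == "hue") {
    vals <- rgb_to_hsv_image(img)$h
    thr <- otsu_threshold(vals, levels = 360L, range = c(0, 360))
  } else {
    idx <- compute_index(img, name, config)
    vals <- idx$values
    thr <- otsu_threshold(vals, levels = 256L)
  }
  pol <- config$index_polarity[[name]]
  if (is.null(pol)) pol <- "high"
  veg <- if (pol == "high") vals > thr else vals <= thr
  list(mask = binary_mask(matrix(ifelse(veg, 255L, 0L),
                                 nrow(vals), ncol(vals))),
       threshold = thr, index_name = name)
}
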