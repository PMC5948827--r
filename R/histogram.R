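#' @title Hue histogram construction, filtering, and Gaussian fitting
#' @name histogram
#' @description The hue histogram is the central object of the method: 360
#'   one-degree bins (bin `k` covers `[k, k+1)` degrees), filtered to remove
#'   hues with negligible presence, then modeled as a sum of up to two
#'   Gaussian-shaped peaks -- one per color class (soil, vegetation).
NULL

new_hue_histogram <- function(bins, counts, total_pixels, filtered) {
  structure(
    list(bins = as.integer(bins), counts = as.numeric(counts),
         total_pixels = as.integer(total_pixels), filtered = filtered),
    class = "hue_histogram"
  )
}

#' Build the 1-degree hue histogram of an HSV image
#'
#' @param hsv An `hsv_image` from [rgb_to_hsv_image()], or a numeric
#'   matrix/vector of hue values in degrees `[0, 360)`.
#' @return A `hue_histogram`: integer `bins` (0..359), `counts` summing to the
#'   pixel count, `total_pixels`, and `filtered = FALSE`. All 360 bins are
#'   present at this stage, including empty ones.
#' @export
build_hue_histogram <- function(hsv) {
  h <- if (inherits(hsv, "hsv_image")) hsv$h else hsv
  h <- as.numeric(h)
  if (anyNA(h) || any(h < 0) || any(h >= 360)) {
    stop("hue values must lie in [0, 360)", call. = FALSE)
  }
  counts <- tabulate(floor(h) + 1L, nbins = 360L)
  new_hue_histogram(0:359, counts, length(h), filtered = FALSE)
}

#' @export
print.hue_histogram <- function(x, ...) {
  nz <- x$counts > 0
  cat(sprintf("<hue_histogram: %d bins (%d nonzero), %d pixels%s>\n",
              length(x$bins), sum(nz), x$total_pixels,
              if (x$filtered) ", filtered" else ""))
  invisible(x)
}

#' Remove small-presence hue values from a histogram
#'
#' A hue bin holding strictly fewer pixels than `filter_fraction` of the image
#' (default 0.001\%) is treated as an outlier color and removed from the bin
#' sequence entirely -- surviving bins keep their counts and later valley
#' walks treat survivors as consecutive.
#'
#' @param h An unfiltered `hue_histogram`.
#' @param config Optional [hueseg_config()] (`filter_fraction`).
#' @return The filtered `hue_histogram` (`filtered = TRUE`).
#' @export
filter_hue_histogram <- function(h, config = NULL) {
  config <- as_hueseg_config(config)
  stopifnot(inherits(h, "hue_histogram"))
  if (h$filtered) return(h)
  # compare on the fraction scale so exact boundary counts are retained
  # (count/total and the configured fraction round to the same double)
  keep <- h$counts > 0 &
    (h$counts / h$total_pixels) >= config$filter_fraction
  if (!any(keep)) {
    stop("degenerate histogram: every hue bin fell below the presence cutoff",
         call. = FALSE)
  }
  new_hue_histogram(h$bins[keep], h$counts[keep], h$total_pixels,
                    filtered = TRUE)
}

#' Export / import a hue histogram as two-column CSV
#'
#' @param h A `hue_histogram`.
#' @param path CSV destination (`bin,count` header).
#' @export
write_hue_histogram <- function(h, path) {
  stopifnot(inherits(h, "hue_histogram"))
  utils::write.csv(data.frame(bin = h$bins, count = h$counts), path,
                   row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_hue_histogram
#' @param total_pixels Pixel count of the source image; defaults to the count
#'   sum (correct for unfiltered histograms).
#' @param filtered Whether the stored histogram had been filtered.
#' @export
read_hue_histogram <- function(path, total_pixels = NULL, filtered = FALSE) {
  df <- utils::read.csv(path)
  if (is.null(total_pixels)) total_pixels <- sum(df$count)
  new_hue_histogram(df$bin, df$count, total_pixels, filtered = filtered)
}

# Gaussian peak model. The literal model form is
#   y = sum_i a_i * exp(-((x - b_i) / c_i)^2)
# so the width parameter c equals sqrt(2) * sigma of the corresponding normal
# density; the confidence-interval logic uses sigma = c / sqrt(2). A config
# switch selects the conventional half-exponent form instead.
gauss_term <- function(x, a, b, c, half_exponent = FALSE) {
  e <- ((x - b) / c)^2
  if (half_exponent) e <- e / 2
  a * exp(-e)
}

#' Fit up to two Gaussian peaks to a filtered hue histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nlsLM()]) of the two-term peak model
#' `y = a1 exp(-((x-b1)/c1)^2) + a2 exp(-((x-b2)/c2)^2)` to the surviving
#' `(bin, count)` pairs. Components are ordered by amplitude, so component 1
#' is the dominant color class. The second component is discarded
#' (`n_peaks = 1`, after a one-term refit) when it is implausible: amplitude
#' below `amp_ratio_min` of the dominant one, centroid outside `[0, 360)`,
#' width above `max_width`, or the two centroids closer than
#' `min_separation` (two heavily overlapping components describe a single
#' peak, not two classes).
#'
#' Starting values: the dominant centroid at the highest-count bin, the
#' second at the highest-count bin at least 30 degrees away, amplitudes at
#' those counts, widths at 10 degrees; up to `n_restarts` jittered restarts
#' (seeded with `fit_seed`, in a local RNG scope) are attempted before
#' falling back to raw-histogram peak picking with `converged = FALSE`.
#'
#' @param h A filtered `hue_histogram` with at least 4 surviving bins.
#' @param config Optional [hueseg_config()].
#' @return A `gaussian_fit` list: `a`, `b`, `c` (length `n_peaks`, amplitude
#'   descending), `n_peaks` (1 or 2), `sigma` (`c / sqrt(2)` under the
#'   default model form), `converged`, `residual_norm`.
#' @export
fit_hue_gaussians <- function(h, config = NULL) {
  config <- as_hueseg_config(config)
  stopifnot(inherits(h, "hue_histogram"))
  if (!h$filtered) {
    stop("histogram must be filtered before fitting", call. = FALSE)
  }
  if (length(h$bins) < 4L) {
    stop("need at least 4 surviving bins to fit", call. = FALSE)
  }
  x <- as.numeric(h$bins)
  y <- h$counts
  half <- config$gauss_half_exponent

  i1 <- which.max(y)
  far <- abs(x - x[i1]) >= 30
  i2 <- if (any(far)) which(far)[which.max(y[far])] else NULL

  start2 <- if (!is.null(i2)) {
    list(a1 = y[i1], b1 = x[i1], c1 = 10,
         a2 = y[i2], b2 = x[i2], c2 = 10)
  } else NULL

  fit_once <- function(start, n_terms) {
    form <- if (n_terms == 2L) {
      y ~ gauss_term(x, a1, b1, c1, half) + gauss_term(x, a2, b2, c2, half)
    } else {
      y ~ gauss_term(x, a1, b1, c1, half)
    }
    lower <- if (n_terms == 2L) c(0, 0, 0.25, 0, 0, 0.25) else c(0, 0, 0.25)
    upper <- if (n_terms == 2L) {
      c(Inf, 359, 360, Inf, 359, 360)
    } else c(Inf, 359, 360)
    tryCatch(
      minpack.lm::nlsLM(
        form, data = list(x = x, y = y, half = half), start = start,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  jitters <- function(start, k) {
    # deterministic jitter sequence drawn in a local RNG scope
    withr::with_seed(config$fit_seed + k, {
      st <- start
      for (nm in grep("^b", names(st), value = TRUE)) {
        st[[nm]] <- min(359, max(0, st[[nm]] + stats::runif(1, -15, 15)))
      }
      for (nm in grep("^c", names(st), value = TRUE)) {
        st[[nm]] <- st[[nm]] * stats::runif(1, 0.5, 2)
      }
      st
    })
  }

  best <- NULL
  if (!is.null(start2)) {
    best <- fit_once(start2, 2L)
    k <- 0L
    while (is.null(best) && k < config$n_restarts) {
      k <- k + 1L
      best <- fit_once(jitters(start2, k), 2L)
    }
  }

  finalize <- function(a, b, cc, n_peaks, converged, resid) {
    ord <- order(a, decreasing = TRUE)
    a <- a[ord]; b <- b[ord]; cc <- cc[ord]
    sigma <- cc / (if (half) 1 else sqrt(2))
    structure(
      list(a = a, b = b, c = cc, n_peaks = n_peaks, sigma = sigma,
           converged = converged, residual_norm = resid,
           half_exponent = half),
      class = "gaussian_fit"
    )
  }

  if (!is.null(best)) {
    p <- stats::coef(best)
    a <- c(p[["a1"]], p[["a2"]]); b <- c(p[["b1"]], p[["b2"]])
    cc <- c(p[["c1"]], p[["c2"]])
    ord <- order(a, decreasing = TRUE)
    a <- a[ord]; b <- b[ord]; cc <- cc[ord]
    drop2 <- a[2] < config$amp_ratio_min * a[1] ||
      b[2] < 0 || b[2] >= 360 ||
      cc[2] > config$max_width ||
      abs(b[1] - b[2]) < config$min_separation
    if (!drop2) {
      resid <- sqrt(sum(stats::resid(best)^2))
      return(finalize(a, b, cc, 2L, TRUE, resid))
    }
  }

  # one-peak refit (either the two-term fit failed or component 2 was
  # implausible)
  start1 <- list(a1 = y[i1], b1 = x[i1], c1 = 10)
  one <- fit_once(start1, 1L)
  k <- 0L
  while (is.null(one) && k < config$n_restarts) {
    k <- k + 1L
    one <- fit_once(jitters(start1, k), 1L)
  }
  if (!is.null(one)) {
    p <- stats::coef(one)
    resid <- sqrt(sum(stats::resid(one)^2))
    return(finalize(p[["a1"]], p[["b1"]], p[["c1"]], 1L, TRUE, resid))
  }

  # last-resort fallback: raw-histogram peak picking, flagged non-converged
  n_pk <- if (!is.null(i2) && y[i2] >= config$amp_ratio_min * y[i1]) 2L else 1L
  a <- y[i1]; b <- x[i1]; cc <- 10
  if (n_pk == 2L) {
    a <- c(a, y[i2]); b <- c(b, x[i2]); cc <- c(cc, 10)
  }
  finalize(a, b, cc, n_pk, FALSE, sqrt(sum(y^2)))
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit: %d peak(s)%s>\n", x$n_peaks,
              if (x$converged) "" else " [not converged]"))
  for (i in seq_len(x$n_peaks)) {
    cat(sprintf("  a=%.1f  b=%.2f deg  c=%.2f  sigma=%.2f\n",
                x$a[i], x$b[i], x$c[i], x$sigma[i]))
  }
  invisible(x)
}

#' Evaluate a fitted Gaussian peak model at given hue values
#'
#' Returns `sum_i a_i * exp(-((x - b_i)/c_i)^2)` (or the half-exponent form
#' if the fit used it), on the pixel-count scale of the histogram.
#'
#' @param fit A `gaussian_fit` from [fit_hue_gaussians()].
#' @param x Hue values in degrees.
#' @return Numeric vector of model values.
#' @export
evaluate_fit <- function(fit, x) {
  stopifnot(inherits(fit, "gaussian_fit"))
  half <- isTRUE(fit$half_exponent)
  out <- numeric(length(x))
  for (i in seq_len(fit$n_peaks)) {
    out <- out + gauss_term(x, fit$a[i], fit$b[i], fit$c[i], half)
  }
  out
}
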