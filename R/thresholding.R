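#' @title Candidate threshold detection and combination
#' @name thresholding
#' @description The method reads two pictures of the same hue distribution --
#'   the fitted Gaussian curve and the filtered histogram -- and extracts up
#'   to five candidate thresholds marking the border of the dominant color
#'   class: `th1` (dominant centroid plus the largest admissible confidence
#'   interval), `th2` (the valley of the fitted curve between the two peaks),
#'   and `th3`/`th4`/`th5` (three local-minimum rules walked along the
#'   surviving histogram bins). Present candidates are averaged into the
#'   final binarization threshold.
NULL

#' Classify the dominant color class and the threshold search direction
#'
#' The dominant class is read off the dominant fitted centroid
#' (`mean_dominant`): vegetation when it is at or beyond the green boundary
#' (60 degrees, green running from yellow at 60 to cyan at 180), otherwise
#' non-vegetation (soil). The threshold is searched toward the *other*
#' class's hue region: increasing hue when soil dominates, decreasing hue
#' when vegetation dominates.
#'
#' @param fit A `gaussian_fit` (converged or fallback).
#' @param h The filtered `hue_histogram`.
#' @param config Optional [hueseg_config()] (`veg_boundary`).
#' @return A `dominant_class_info` list: `mean_dominant`, `main_hue` (highest
#'   surviving bin), `dominant_class` (`"vegetation"`/`"non_vegetation"`),
#'   `direction` (`"increasing_hue"`/`"decreasing_hue"`).
#' @export
classify_dominant <- function(fit, h, config = NULL) {
  config <- as_hueseg_config(config)
  stopifnot(inherits(fit, "gaussian_fit"), inherits(h, "hue_histogram"))
  main_hue <- h$bins[which.max(h$counts)]
  mean_dominant <- fit$b[1]
  veg <- mean_dominant >= config$veg_boundary
  structure(
    list(
      mean_dominant = mean_dominant,
      main_hue = as.numeric(main_hue),
      dominant_class = if (veg) "vegetation" else "non_vegetation",
      direction = if (veg) "decreasing_hue" else "increasing_hue"
    ),
    class = "dominant_class_info"
  )
}

#' Classify the image case
#'
#' Four cases span peak count x dominant class: case 1 = one peak, soil
#' dominant; case 2 = one peak, vegetation dominant; case 3 = two peaks, soil
#' dominant; case 4 = two peaks, vegetation dominant.
#'
#' @param fit A `gaussian_fit`.
#' @param dom A `dominant_class_info`.
#' @return `"case1"`, `"case2"`, `"case3"`, or `"case4"`.
#' @export
classify_case <- function(fit, dom) {
  veg <- dom$dominant_class == "vegetation"
  if (fit$n_peaks == 1L) {
    if (veg) "case2" else "case1"
  } else {
    if (veg) "case4" else "case3"
  }
}

# S2: distance from the dominant centroid to the far end of the dominant
# distribution, on the side OPPOSITE the search direction. Used as the
# goodness gate for the confidence-interval threshold: a symmetric Gaussian
# whose k-sigma interval does not fit inside S2 was not fitted credibly.
s2_distance <- function(fit, dom, h, config) {
  if (config$s2_mode == "fit3sigma") {
    return(3 * fit$sigma[1])
  }
  if (dom$direction == "increasing_hue") {
    dom$mean_dominant - min(h$bins)
  } else {
    max(h$bins) - dom$mean_dominant
  }
}

#' Confidence-interval threshold of the dominant Gaussian (th1)
#'
#' `th1 = mean_dominant +/- k * sigma` along the search direction, with
#' `sigma` the standard deviation of the dominant fitted peak and `k` the
#' *highest allowable* multiple among `sigma_multiples` (default 3, 2, 1):
#' a multiple is admissible only when `k * sigma < S2`, the distance from the
#' centroid to the end of the histogram support opposite the search
#' direction. If no multiple is admissible `th1` is absent.
#'
#' @param fit A converged `gaussian_fit`.
#' @param dom A `dominant_class_info`.
#' @param h The filtered `hue_histogram`.
#' @param config Optional [hueseg_config()].
#' @return List: `th1` (degrees or `NA`), `k` (chosen multiple or `NA`),
#'   `s2` (degrees).
#' @export
detect_th1 <- function(fit, dom, h, config = NULL) {
  config <- as_hueseg_config(config)
  sigma <- fit$sigma[1]
  s2 <- s2_distance(fit, dom, h, config)
  k <- NA_real_
  for (m in sort(config$sigma_multiples, decreasing = TRUE)) {
    if (m * sigma < s2) { k <- m; break }
  }
  th1 <- if (is.na(k)) NA_real_ else {
    if (dom$direction == "increasing_hue") dom$mean_dominant + k * sigma
    else dom$mean_dominant - k * sigma
  }
  list(th1 = th1, k = k, s2 = s2)
}

#' Valley of the fitted curve between the two peaks (th2)
#'
#' Absent unless the fit has two peaks and the second centroid lies in the
#' search direction from the dominant one. Otherwise `th2` is the hue
#' minimizing the fitted curve on the closed interval between the two
#' centroids (0.1-degree grid scan followed by local refinement).
#'
#' @inheritParams detect_th1
#' @return `th2` in degrees, or `NA` when absent.
#' @export
detect_th2 <- function(fit, dom, config = NULL) {
  config <- as_hueseg_config(config)
  if (fit$n_peaks < 2L) return(NA_real_)
  # anchor on the dominant (larger-amplitude) component so that relabeling
  # the two components never changes the result
  i_dom <- which.max(fit$a[1:2])
  b1 <- fit$b[i_dom]; b2 <- fit$b[3L - i_dom]
  in_dir <- if (dom$direction == "increasing_hue") b2 > b1 else b2 < b1
  if (!in_dir) return(NA_real_)
  lo <- min(b1, b2); hi <- max(b1, b2)
  grid <- seq(lo, hi, by = 0.1)
  yv <- evaluate_fit(fit, grid)
  i <- which.min(yv)
  a <- grid[max(1L, i - 1L)]; b <- grid[min(length(grid), i + 1L)]
  if (a == b) return(grid[i])
  stats::optimize(function(z) evaluate_fit(fit, z),
                  interval = c(a, b))$minimum
}

#' Enumerate valleys and peaks along the histogram walk
#'
#' Starting at the highest surviving bin (`main_hue`) and walking the
#' surviving bins in the search direction, consecutive equal counts are
#' collapsed to their first bin (plateau rule); a collapsed run strictly
#' lower than both neighboring runs is a valley, strictly higher a peak.
#' Endpoint runs are neither. Valleys and peaks strictly alternate along the
#' walk.
#'
#' @param h A filtered `hue_histogram`.
#' @param dom A `dominant_class_info`.
#' @return List with data frames `valleys` and `peaks` (`hue`, `count`,
#'   `pos` = index into the walk), plus the walk itself (`walk_bins`,
#'   `walk_counts`). Fewer than 3 surviving bins beyond `main_hue` yields
#'   empty sequences.
#' @export
enumerate_valleys_peaks <- function(h, dom) {
  stopifnot(inherits(h, "hue_histogram"))
  empty <- data.frame(hue = numeric(0), count = numeric(0), pos = integer(0))
  if (dom$direction == "increasing_hue") {
    sel <- h$bins >= dom$main_hue
    ord <- order(h$bins[sel])
  } else {
    sel <- h$bins <= dom$main_hue
    ord <- order(h$bins[sel], decreasing = TRUE)
  }
  walk_bins <- h$bins[sel][ord]
  walk_counts <- h$counts[sel][ord]
  out <- list(valleys = empty, peaks = empty,
              walk_bins = walk_bins, walk_counts = walk_counts)
  if (length(walk_bins) - 1L < 3L) return(out)

  r <- rle(walk_counts)
  n <- length(r$values)
  if (n < 3L) return(out)
  run_start <- cumsum(c(1L, r$lengths[-n]))  # walk index of each run's first bin
  for (i in 2:(n - 1L)) {
    v <- r$values[i]
    if (v < r$values[i - 1L] && v < r$values[i + 1L]) {
      out$valleys <- rbind(out$valleys, data.frame(
        hue = walk_bins[run_start[i]], count = v, pos = run_start[i]))
    } else if (v > r$values[i - 1L] && v > r$values[i + 1L]) {
      out$peaks <- rbind(out$peaks, data.frame(
        hue = walk_bins[run_start[i]], count = v, pos = run_start[i]))
    }
  }
  out
}

# Average the stops surviving the 30-70 degree admissibility window.
average_admissible <- function(stops, config) {
  if (!length(stops)) return(NA_real_)
  keep <- stops >= config$stop_bounds[1] & stops <= config$stop_bounds[2]
  if (!any(keep)) return(NA_real_)
  mean(stops[keep])
}

#' Valley-below-next-valley threshold (th3)
#'
#' Every valley whose pixel count is lower than the next valley's count along
#' the walk is a candidate stop; stops are filtered to the admissible hue
#' window (30-70 degrees by default) and averaged.
#'
#' @inheritParams enumerate_valleys_peaks
#' @param config Optional [hueseg_config()] (`stop_bounds`).
#' @return List: `th3` (degrees or `NA`), `stops` (all stops, pre-filter).
#' @export
detect_th3 <- function(h, dom, config = NULL) {
  config <- as_hueseg_config(config)
  vp <- enumerate_valleys_peaks(h, dom)
  v <- vp$valleys
  stops <- numeric(0)
  if (nrow(v) >= 2L) {
    for (i in 1:(nrow(v) - 1L)) {
      if (v$count[i] < v$count[i + 1L]) stops <- c(stops, v$hue[i])
    }
  }
  list(th3 = average_admissible(stops, config), stops = stops)
}

#' Valley-followed-by-two-rises threshold (th4)
#'
#' A valley is a candidate stop when the two surviving bins immediately after
#' it in the walk have strictly increasing counts (two successive uprisings).
#' Plateau valleys (equal-count runs) therefore never qualify. Stops are
#' filtered to the admissible window and averaged.
#'
#' @inheritParams detect_th3
#' @return List: `th4` (degrees or `NA`), `stops`.
#' @export
detect_th4 <- function(h, dom, config = NULL) {
  config <- as_hueseg_config(config)
  vp <- enumerate_valleys_peaks(h, dom)
  v <- vp$valleys
  cnt <- vp$walk_counts
  stops <- numeric(0)
  if (nrow(v)) {
    for (i in seq_len(nrow(v))) {
      p <- v$pos[i]
      if (p + 2L <= length(cnt) &&
          cnt[p + 1L] > cnt[p] && cnt[p + 2L] > cnt[p + 1L]) {
        stops <- c(stops, v$hue[i])
      }
    }
  }
  list(th4 = average_admissible(stops, config), stops = stops)
}

#' Smaller-valley-around-rising-peak threshold (th5)
#'
#' For every peak whose count is lower than the next peak's count, the
#' valleys immediately before and after it (in the walk's alternating
#' extremum sequence) are compared and the one holding fewer pixels becomes a
#' candidate stop (ties go to the earlier valley). Stops are filtered to the
#' admissible window and averaged.
#'
#' @inheritParams detect_th3
#' @return List: `th5` (degrees or `NA`), `stops`.
#' @export
detect_th5 <- function(h, dom, config = NULL) {
  config <- as_hueseg_config(config)
  vp <- enumerate_valleys_peaks(h, dom)
  pk <- vp$peaks; v <- vp$valleys
  stops <- numeric(0)
  if (nrow(pk) >= 2L) {
    for (i in 1:(nrow(pk) - 1L)) {
      if (pk$count[i] < pk$count[i + 1L]) {
        before <- v[v$pos < pk$pos[i], , drop = FALSE]
        after <- v[v$pos > pk$pos[i], , drop = FALSE]
        if (nrow(before) && nrow(after)) {
          vb <- before[nrow(before), ]  # nearest valley before the peak
          va <- after[1L, ]             # nearest valley after
          stops <- c(stops, if (vb$count <= va$count) vb$hue else va$hue)
        }
      }
    }
  }
  list(th5 = average_admissible(stops, config), stops = stops)
}

#' Run the full threshold-detection stage on a filtered histogram
#'
#' Classifies the dominant class and image case, detects the five candidate
#' thresholds, and combines the present ones into the final threshold by an
#' unweighted mean. `th2` requires two fitted peaks; each of the others may
#' be absent on a given image. If no candidate is present the function either
#' errors or, with `fallback_otsu = TRUE`, substitutes the Otsu threshold of
#' the hue histogram (flagged in the report).
#'
#' @param fit A `gaussian_fit`.
#' @param h The filtered `hue_histogram`.
#' @param config Optional [hueseg_config()].
#' @return A `threshold_report` list: `th1`..`th5` (degrees or `NA`),
#'   `th3_stops`, `th4_stops`, `th5_stops`, `chosen_sigma_multiple`, `s2`,
#'   `case`, `dominant` (the `dominant_class_info`), `final_threshold`,
#'   `used_fallback`.
#' @export
detect_thresholds <- function(fit, h, config = NULL) {
  config <- as_hueseg_config(config)
  dom <- classify_dominant(fit, h, config)
  case <- classify_case(fit, dom)
  r1 <- detect_th1(fit, dom, h, config)
  th2 <- detect_th2(fit, dom, config)
  r3 <- detect_th3(h, dom, config)
  r4 <- detect_th4(h, dom, config)
  r5 <- detect_th5(h, dom, config)
  th1 <- r1$th1
  if (config$bounds_all_candidates) {
    inb <- function(z) {
      if (!is.na(z) && (z < config$stop_bounds[1] || z > config$stop_bounds[2]))
        NA_real_ else z
    }
    th1 <- inb(th1); th2 <- inb(th2)
  }
  cand <- c(th1 = th1, th2 = th2, th3 = r3$th3, th4 = r4$th4, th5 = r5$th5)
  used_fallback <- FALSE
  if (all(is.na(cand))) {
    if (!config$fallback_otsu) {
      stop("threshold detection failed: no candidate threshold present",
           call. = FALSE)
    }
    final <- otsu_threshold(rep(h$bins, times = pmax(1, round(h$counts))),
                            levels = 360L, range = c(0, 360))
    used_fallback <- TRUE
  } else {
    final <- mean(cand, na.rm = TRUE)
  }
  structure(
    list(
      th1 = unname(th1), th2 = unname(th2), th3 = r3$th3, th4 = r4$th4,
      th5 = r5$th5,
      th3_stops = r3$stops, th4_stops = r4$stops, th5_stops = r5$stops,
      chosen_sigma_multiple = r1$k, s2 = r1$s2,
      case = case, dominant = dom,
      final_threshold = final, used_fallback = used_fallback
    ),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  fmt <- function(z) if (is.na(z)) "N/A" else sprintf("%.2f", z)
  cat(sprintf("<threshold_report: %s, dominant %s, search %s>\n",
              x$case, x$dominant$dominant_class, x$dominant$direction))
  cat(sprintf("  th1=%s (k=%s, S2=%.1f)  th2=%s  th3=%s  th4=%s  th5=%s\n",
              fmt(x$th1), ifelse(is.na(x$chosen_sigma_multiple), "N/A",
                                 x$chosen_sigma_multiple),
              x$s2, fmt(x$th2), fmt(x$th3), fmt(x$th4), fmt(x$th5)))
  cat(sprintf("  final threshold: %.2f deg%s\n", x$final_threshold,
              if (x$used_fallback) " [Otsu fallback]" else ""))
  invisible(x)
}

#' Serialize / restore a threshold report as JSON
#'
#' @param report A `threshold_report`.
#' @param path Destination JSON path.
#' @export
write_threshold_report <- function(report, path) {
  stopifnot(inherits(report, "threshold_report"))
  obj <- unclass(report)
  obj$dominant <- unclass(obj$dominant)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(NULL)
}

#' @rdname write_threshold_report
#' @export
read_threshold_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  null_to_na <- function(z) if (is.null(z)) NA_real_ else z
  for (f in c("th1", "th2", "th3", "th4", "th5", "chosen_sigma_multiple")) {
    obj[[f]] <- null_to_na(obj[[f]])
  }
  for (f in c("th3_stops", "th4_stops", "th5_stops")) {
    if (is.null(obj[[f]])) obj[[f]] <- numeric(0)
  }
  obj$dominant <- structure(obj$dominant, class = "dominant_class_info")
  structure(obj, class = "threshold_report")
}
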