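# Independent reference implementations used as oracles. These are written
# as plain per-element loops, deliberately sharing no code with the package.

# Scalar hexcone RGB -> HSV reference (one pixel at a time).
oracle_rgb_to_hsv <- function(R, G, B) {
  rp <- R / 255; gp <- G / 255; bp <- B / 255
  M <- max(rp, gp, bp)
  m <- min(rp, gp, bp)
  C <- M - m
  if (C == 0) {
    H <- 0
  } else if (M == rp) {
    H <- 60 * (((gp - bp) / C) %% 6)
  } else if (M == gp) {
    H <- 60 * ((bp - rp) / C + 2)
  } else {
    H <- 60 * ((rp - gp) / C + 4)
  }
  if (H >= 360) H <- 0
  S <- if (M == 0) 0 else C / M
  c(h = H, s = S, v = M)
}

# Exhaustive between-class-variance search over every quantized split.
oracle_otsu <- function(x, levels = 256L, range = NULL) {
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  step <- (hi - lo) / levels
  lev <- pmin(levels - 1L, floor((as.numeric(x) - lo) / step))
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:(levels - 2L)) {
    g0 <- lev <= t
    n0 <- sum(g0); n1 <- sum(!g0)
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(lev); w1 <- 1 - w0
    mid <- lo + (0:(levels - 1L) + 0.5) * step
    mu0 <- mean(mid[lev[g0] + 1L])
    mu1 <- mean(mid[lev[!g0] + 1L])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  if (is.na(best_t)) stop("oracle: degenerate image")
  lo + (best_t + 1L) * step
}

# Plain-loop extremum finder on a walk of counts: collapse equal-count runs
# to their first walk index, then compare each interior run to neighbors.
oracle_extrema <- function(counts) {
  runs_val <- c(); runs_start <- c()
  i <- 1L
  while (i <= length(counts)) {
    j <- i
    while (j < length(counts) && counts[j + 1L] == counts[i]) j <- j + 1L
    runs_val <- c(runs_val, counts[i])
    runs_start <- c(runs_start, i)
    i <- j + 1L
  }
  valleys <- c(); peaks <- c()
  if (length(runs_val) >= 3L) {
    for (k in 2:(length(runs_val) - 1L)) {
      if (runs_val[k] < runs_val[k - 1L] && runs_val[k] < runs_val[k + 1L]) {
        valleys <- c(valleys, runs_start[k])
      }
      if (runs_val[k] > runs_val[k - 1L] && runs_val[k] > runs_val[k + 1L]) {
        peaks <- c(peaks, runs_start[k])
      }
    }
  }
  list(valleys = valleys, peaks = peaks)  # walk indices of run-first bins
}

# Stop rules applied literally to walk bins/counts.
oracle_th3_stops <- function(bins, counts) {
  ex <- oracle_extrema(counts)
  v <- ex$valleys
  stops <- c()
  if (length(v) >= 2L) {
    for (i in 1:(length(v) - 1L)) {
      if (counts[v[i]] < counts[v[i + 1L]]) stops <- c(stops, bins[v[i]])
    }
  }
  stops
}

oracle_th4_stops <- function(bins, counts) {
  ex <- oracle_extrema(counts)
  stops <- c()
  for (p in ex$valleys) {
    if (p + 2L <= length(counts) &&
        counts[p + 1L] > counts[p] && counts[p + 2L] > counts[p + 1L]) {
      stops <- c(stops, bins[p])
    }
  }
  stops
}

oracle_th5_stops <- function(bins, counts) {
  ex <- oracle_extrema(counts)
  pk <- ex$peaks; v <- ex$valleys
  stops <- c()
  if (length(pk) >= 2L) {
    for (i in 1:(length(pk) - 1L)) {
      if (counts[pk[i]] < counts[pk[i + 1L]]) {
        before <- v[v < pk[i]]
        after <- v[v > pk[i]]
        if (length(before) && length(after)) {
          vb <- before[length(before)]
          va <- after[1L]
          stops <- c(stops, if (counts[vb] <= counts[va]) bins[vb]
                     else bins[va])
        }
      }
    }
  }
  stops
}

# Random filtered histogram with a marked main hue, for rule-oracle checks.
random_filtered_histogram <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(15:80, 1)
    bins <- sort(sample(0:359, n))
    counts <- sample(1:500, n, replace = TRUE)
    main_i <- sample(seq_len(n), 1)
    counts[main_i] <- max(counts) + sample(1:100, 1)
    h <- structure(
      list(bins = as.integer(bins), counts = as.numeric(counts),
           total_pixels = as.integer(sum(counts)), filtered = TRUE),
      class = "hue_histogram"
    )
    dir <- sample(c("increasing_hue", "decreasing_hue"), 1)
    dom <- structure(
      list(mean_dominant = bins[main_i], main_hue = bins[main_i],
           dominant_class = if (dir == "increasing_hue") "non_vegetation"
                            else "vegetation",
           direction = dir),
      class = "dominant_class_info"
    )
    list(h = h, dom = dom)
  })
}

# Walk (bins and counts ordered from main_hue in the search direction), as
# plain subsetting, for feeding the stop oracles.
oracle_walk <- function(h, dom) {
  if (dom$direction == "increasing_hue") {
    sel <- h$bins >= dom$main_hue
    ord <- order(h$bins[sel])
  } else {
    sel <- h$bins <= dom$main_hue
    ord <- order(h$bins[sel], decreasing = TRUE)
  }
  list(bins = h$bins[sel][ord], counts = h$counts[sel][ord])
}

# A two-class scene small enough for fast tests.
tiny_scene <- function(seed = 1, frac = 0.4, n = 96, ...) {
  hueseg::generate_field(hueseg::field_spec(height = n, width = n,
                                            veg_fraction = frac,
                                            row_spacing_px = max(4L, n %/% 8L),
                                            seed = seed, ...))
}

# Mode of a histogram after light smoothing (5-bin moving average), a
# lower-variance estimate of the class hue mode than the raw argmax.
smoothed_mode <- function(h, lo = 0, hi = 360) {
  sel <- h$bins >= lo & h$bins < hi
  bins <- h$bins[sel]; counts <- h$counts[sel]
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  bins[which.max(sm)]
}

# Independent single-term evaluation of the literal peak model.
gauss_term_ref <- function(x, a, b, cc) a * exp(-((x - b) / cc)^2)

# Filtered histogram of a small two-class scene (soil-dominant).
make_separable_hist <- function(seed = 5, frac = 0.35, n = 128) {
  sc <- tiny_scene(seed = seed, frac = frac, n = n)
  hsv <- hueseg::rgb_to_hsv_image(sc$image)
  hueseg::filter_hue_histogram(hueseg::build_hue_histogram(hsv))
}
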