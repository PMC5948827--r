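# A converged fit object built directly, for exercising the decision rules.
fake_fit <- function(a, b, cc, n_peaks = length(a)) {
  structure(list(a = a, b = b, c = cc, n_peaks = as.integer(n_peaks),
                 sigma = cc / sqrt(2), converged = TRUE, residual_norm = 0,
                 half_exponent = FALSE),
            class = "gaussian_fit")
}

fake_hist <- function(bins, counts) {
  structure(list(bins = as.integer(bins), counts = as.numeric(counts),
                 total_pixels = as.integer(sum(counts)), filtered = TRUE),
            class = "hue_histogram")
}

test_that("dominant class, search direction, and case follow the 60-degree rule", {
  h <- fake_hist(c(30, 40, 50, 110), c(10, 100, 10, 5))
  soil <- classify_dominant(fake_fit(100, 45, 10), h)
  expect_equal(soil$dominant_class, "non_vegetation")
  expect_equal(soil$direction, "increasing_hue")
  expect_equal(soil$main_hue, 40)

  veg <- classify_dominant(fake_fit(100, 110, 10), h)
  expect_equal(veg$dominant_class, "vegetation")
  expect_equal(veg$direction, "decreasing_hue")

  # boundary hue 60 is vegetation (green starts at yellow = 60)
  expect_equal(classify_dominant(fake_fit(100, 60, 10), h)$dominant_class,
               "vegetation")

  one <- fake_fit(100, 45, 10)
  two <- fake_fit(c(100, 50), c(45, 120), c(10, 10))
  expect_equal(classify_case(one, soil), "case1")
  expect_equal(classify_case(one, veg), "case2")
  expect_equal(classify_case(two, soil), "case3")
  expect_equal(classify_case(two, veg), "case4")
})

test_that("th1 takes the highest sigma multiple admissible under S2", {
  # S2 from histogram support: mean 40, support starts at 10 -> S2 = 30
  h <- fake_hist(c(10, 40, 90), c(5, 100, 3))
  dom <- structure(list(mean_dominant = 40, main_hue = 40,
                        dominant_class = "non_vegetation",
                        direction = "increasing_hue"),
                   class = "dominant_class_info")
  # sigma = 8: 3*8 = 24 < 30 -> k = 3, th1 = 64
  r <- detect_th1(fake_fit(100, 40, 8 * sqrt(2)), dom, h)
  expect_equal(r$s2, 30)
  expect_equal(r$k, 3)
  expect_equal(r$th1, 64)
  # sigma = 12: 36 >= 30 rejected, 24 < 30 -> k = 2, th1 = 64
  r <- detect_th1(fake_fit(100, 40, 12 * sqrt(2)), dom, h)
  expect_equal(r$k, 2)
  expect_equal(r$th1, 64)
  # sigma = 40: every multiple rejected -> absent
  r <- detect_th1(fake_fit(100, 40, 40 * sqrt(2)), dom, h)
  expect_true(is.na(r$th1))
  expect_true(is.na(r$k))
  # vegetation-dominant search subtracts the interval
  h2 <- fake_hist(c(40, 110, 140), c(3, 100, 5))
  dom2 <- structure(list(mean_dominant = 110, main_hue = 110,
                         dominant_class = "vegetation",
                         direction = "decreasing_hue"),
                    class = "dominant_class_info")
  r <- detect_th1(fake_fit(100, 110, 8 * sqrt(2)), dom2, h2)
  expect_equal(r$s2, 30)
  expect_equal(r$th1, 110 - 24)
})

test_that("th2 is the fitted-curve valley between the two centroids", {
  dom <- structure(list(mean_dominant = 40, main_hue = 40,
                        dominant_class = "non_vegetation",
                        direction = "increasing_hue"),
                   class = "dominant_class_info")
  # absent with one peak
  expect_true(is.na(detect_th2(fake_fit(100, 40, 10), dom)))
  # equal components -> symmetric midpoint
  sym <- fake_fit(c(1000, 1000), c(40, 120), c(12, 12))
  expect_equal(detect_th2(sym, dom), 80, tolerance = 1e-6)
  # asymmetric case vs exhaustive 0.01-degree scan
  fit <- fake_fit(c(5000, 1000), c(40, 120), c(10, 20))
  grid <- seq(40, 120, by = 0.01)
  ref <- grid[which.min(gauss_term_ref(grid, 5000, 40, 10) +
                          gauss_term_ref(grid, 1000, 120, 20))]
  expect_lt(abs(detect_th2(fit, dom) - ref), 0.1)
  # relabeling the components leaves th2 unchanged
  swapped <- fake_fit(c(1000, 5000), c(120, 40), c(20, 10))
  expect_equal(detect_th2(fit, dom), detect_th2(swapped, dom),
               tolerance = 1e-6)
  # second centroid opposite the search direction -> absent
  dom_dec <- structure(list(mean_dominant = 40, main_hue = 40,
                            dominant_class = "vegetation",
                            direction = "decreasing_hue"),
                       class = "dominant_class_info")
  expect_true(is.na(detect_th2(fit, dom_dec)))
})

test_that("valley/peak enumeration matches the definition on a hand case", {
  # walk counts [9, 4, 7, 2, 8]: valleys at 4 and 2, peak at 7
  h <- fake_hist(40:44, c(9, 4, 7, 2, 8))
  dom <- structure(list(mean_dominant = 40, main_hue = 40,
                        dominant_class = "non_vegetation",
                        direction = "increasing_hue"),
                   class = "dominant_class_info")
  vp <- enumerate_valleys_peaks(h, dom)
  expect_equal(vp$valleys$hue, c(41, 43))
  expect_equal(vp$peaks$hue, 42)
  # monotone walk: no extrema
  mono <- fake_hist(40:44, c(9, 8, 7, 6, 5))
  vp2 <- enumerate_valleys_peaks(mono, dom)
  expect_equal(nrow(vp2$valleys), 0)
  expect_equal(nrow(vp2$peaks), 0)
})

test_that("valleys and peaks strictly alternate on random histograms", {
  for (s in 1:100) {
    rh <- random_filtered_histogram(s)
    vp <- enumerate_valleys_peaks(rh$h, rh$dom)
    ext <- rbind(
      if (nrow(vp$valleys)) cbind(vp$valleys, type = "v"),
      if (nrow(vp$peaks)) cbind(vp$peaks, type = "p")
    )
    if (is.null(ext) || nrow(ext) < 2) next
    ext <- ext[order(ext$pos), ]
    expect_true(all(ext$type[-1] != ext$type[-nrow(ext)]),
                info = paste("seed", s))
  }
})

test_that("th3 averages valleys lower than their successor within 30-70 deg", {
  # valleys at hues 45, 55, 65, 75 with counts 100, 300, 50, 400:
  # stops at 45 (100<300) and 65 (50<400); 55 not (300>50); 75 has no next
  bins <- c(40, 45, 50, 55, 60, 65, 70, 75, 80)
  counts <- c(900, 100, 500, 300, 600, 50, 700, 400, 800)
  h <- fake_hist(bins, counts)
  dom <- structure(list(mean_dominant = 40, main_hue = 40,
                        dominant_class = "non_vegetation",
                        direction = "increasing_hue"),
                   class = "dominant_class_info")
  r <- detect_th3(h, dom)
  expect_equal(sort(r$stops), c(45, 65))
  expect_equal(r$th3, 55)
  # all stops outside the admissible window -> absent
  r2 <- detect_th3(h, dom, hueseg_config(stop_bounds = c(80, 90)))
  expect_true(is.na(r2$th3))
})

test_that("th4 requires two successive uprisings after the valley", {
  dom <- structure(list(mean_dominant = 40, main_hue = 40,
                        dominant_class = "non_vegetation",
                        direction = "increasing_hue"),
                   class = "dominant_class_info")
  h <- fake_hist(40:44, c(10, 3, 5, 9, 4))  # valley 3 then 5, 9 -> stop
  expect_equal(detect_th4(h, dom)$stops, 41)
  h2 <- fake_hist(40:45, c(10, 3, 5, 2, 8, 9))  # valley 3: only one rise
  expect_false(41 %in% detect_th4(h2, dom)$stops)
})

test_that("th5 picks the smaller valley flanking a rising peak", {
  dom <- structure(list(mean_dominant = 40, main_hue = 40,
                        dominant_class = "non_vegetation",
                        direction = "increasing_hue"),
                   class = "dominant_class_info")
  # walk 900, 80, 200, 120, 500, 100, 600, 50 has interior peaks 200, 500, 600
  h <- fake_hist(40:47, c(900, 80, 200, 120, 500, 100, 600, 50))
  r <- detect_th5(h, dom)
  # peak 200 (< next peak 500): valleys 80 (before) vs 120 (after) -> 80 at 41
  # peak 500 (< next peak 600): valleys 120 vs 100 -> 100 at 45
  expect_equal(sort(r$stops), c(41, 45))
  # single interior peak -> no stops
  h1 <- fake_hist(40:44, c(900, 80, 200, 120, 500))
  expect_length(detect_th5(h1, dom)$stops, 0)
})

test_that("th3/th4/th5 stop enumeration matches brute force on random histograms", {
  for (s in 1:100) {
    rh <- random_filtered_histogram(s)
    w <- oracle_walk(rh$h, rh$dom)
    skip_walk <- length(w$bins) - 1L < 3L
    exp3 <- if (skip_walk) numeric(0) else oracle_th3_stops(w$bins, w$counts)
    exp4 <- if (skip_walk) numeric(0) else oracle_th4_stops(w$bins, w$counts)
    exp5 <- if (skip_walk) numeric(0) else oracle_th5_stops(w$bins, w$counts)
    expect_equal(detect_th3(rh$h, rh$dom)$stops, as.numeric(exp3),
                 info = paste("th3 seed", s))
    expect_equal(detect_th4(rh$h, rh$dom)$stops, as.numeric(exp4),
                 info = paste("th4 seed", s))
    expect_equal(detect_th5(rh$h, rh$dom)$stops, as.numeric(exp5),
                 info = paste("th5 seed", s))
  }
})

test_that("candidate combination is the unweighted mean of present thresholds", {
  h <- make_separable_hist()
  fit <- fit_hue_gaussians(h)
  rep <- detect_thresholds(fit, h)
  cand <- c(rep$th1, rep$th2, rep$th3, rep$th4, rep$th5)
  expect_true(any(!is.na(cand)))
  expect_equal(rep$final_threshold, mean(cand, na.rm = TRUE))
  span <- range(h$bins)
  expect_gte(rep$final_threshold, span[1])
  expect_lte(rep$final_threshold, span[2])
})

test_that("a report with no candidates errors, or falls back to Otsu when enabled", {
  # dominant mode at the very edge of the support: S2 ~ 0 rejects every
  # sigma multiple, and the monotone walk offers no valleys or peaks
  h <- fake_hist(40:44, c(400, 210, 100, 60, 50))
  fit <- fit_hue_gaussians(h)
  expect_error(detect_thresholds(fit, h), "no candidate")
  rep <- detect_thresholds(fit, h, hueseg_config(fallback_otsu = TRUE))
  expect_true(rep$used_fallback)
  expect_true(is.finite(rep$final_threshold))
})

test_that("threshold reports serialize to JSON and back", {
  tmp <- withr::local_tempdir()
  h <- make_separable_hist()
  fit <- fit_hue_gaussians(h)
  rep <- detect_thresholds(fit, h)
  p <- file.path(tmp, "report.json")
  write_threshold_report(rep, p)
  rep2 <- read_threshold_report(p)
  expect_equal(rep2$final_threshold, rep$final_threshold)
  expect_equal(rep2$case, rep$case)
  expect_equal(rep2$th1, rep$th1)
  expect_equal(rep2$dominant$direction, rep$dominant$direction)
  expect_equal(rep2$th3_stops, rep$th3_stops)
})
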