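test_that("histogram binning is exact and conserves pixel counts", {
  h <- build_hue_histogram(matrix(c(30.2, 30.9, 120.0, 120.4), 2, 2))
  expect_equal(h$counts[h$bins == 30], 2)
  expect_equal(h$counts[h$bins == 120], 2)
  expect_equal(sum(h$counts), 4)
  expect_false(h$filtered)

  uni <- build_hue_histogram(matrix(77.7, 5, 7))
  expect_equal(sum(uni$counts > 0), 1)
  expect_equal(max(uni$counts), 35)
  expect_error(build_hue_histogram(matrix(c(10, 361), 1, 2)), "360")
})

test_that("small-presence filter removes strictly-below-cutoff bins only", {
  # cutoff = 0.001% of 1e7 = 100 pixels
  h <- structure(list(bins = c(40L, 50L, 60L), counts = c(50, 100, 9999850),
                      total_pixels = 10000000L, filtered = FALSE),
                 class = "hue_histogram")
  f <- filter_hue_histogram(h)
  expect_equal(f$bins, c(50L, 60L))   # 50 < 100 removed; 100 kept (not strict)
  expect_equal(f$counts, c(100, 9999850))
  expect_true(f$filtered)

  # filtering is idempotent and never adds bins or increases counts
  expect_identical(filter_hue_histogram(f), f)
  expect_true(all(f$counts %in% h$counts))
  expect_lte(length(f$bins), length(h$bins))

  all_small <- structure(list(bins = 0:3, counts = rep(1, 4),
                              total_pixels = 10000000L, filtered = FALSE),
                         class = "hue_histogram")
  expect_error(filter_hue_histogram(all_small), "degenerate")
})

test_that("histogram CSV export round-trips", {
  tmp <- withr::local_tempdir()
  h <- build_hue_histogram(matrix(c(30.2, 30.9, 120.0, 120.4), 2, 2))
  p <- file.path(tmp, "hist.csv")
  write_hue_histogram(h, p)
  h2 <- read_hue_histogram(p)
  expect_equal(h2$bins, h$bins)
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$total_pixels, h$total_pixels)
})

make_two_gauss_hist <- function(a1, b1, c1, a2, b2, c2, seed = NULL,
                                poisson = FALSE) {
  x <- 0:359
  y <- a1 * exp(-((x - b1) / c1)^2) + a2 * exp(-((x - b2) / c2)^2)
  if (poisson) y <- withr::with_seed(seed, stats::rpois(length(y), y))
  keep <- y > max(1e-6, 1e-5 * sum(y))
  structure(list(bins = x[keep], counts = as.numeric(y[keep]),
                 total_pixels = as.integer(round(sum(y))), filtered = TRUE),
            class = "hue_histogram")
}

test_that("noiseless two-Gaussian histograms are recovered nearly exactly", {
  h <- make_two_gauss_hist(5000, 40, 10, 2000, 120, 15)
  fit <- fit_hue_gaussians(h)
  expect_true(fit$converged)
  expect_equal(fit$n_peaks, 2L)
  expect_lt(abs(fit$b[1] - 40), 0.1)
  expect_lt(abs(fit$b[2] - 120), 0.1)
  expect_gte(fit$a[1], fit$a[2])  # dominant component first
  expect_lt(fit$residual_norm, 1e-6 * 5000)
})

test_that("a pure single Gaussian yields one peak with centroid within 0.5 deg", {
  h <- make_two_gauss_hist(4000, 85, 12, 0, 0, 1)
  fit <- fit_hue_gaussians(h)
  expect_true(fit$converged)
  expect_equal(fit$n_peaks, 1L)
  expect_lt(abs(fit$b[1] - 85), 0.5)
})

test_that("centroids are recovered under Poisson noise (seeded recovery study)", {
  errs <- sapply(1:50, function(s) {
    pars <- withr::with_seed(1000 + s, {
      b1 <- runif(1, 20, 150)
      gap <- runif(1, 40, 120) * sample(c(-1, 1), 1)
      b2 <- min(340, max(10, b1 + gap))
      c(a1 = runif(1, 3000, 8000), b1 = b1, c1 = runif(1, 6, 20),
        a2 = runif(1, 500, 2500), b2 = b2, c2 = runif(1, 6, 20))
    })
    if (abs(pars[["b2"]] - pars[["b1"]]) < 40) return(NA)  # keep separation >= 40
    h <- make_two_gauss_hist(pars[["a1"]], pars[["b1"]], pars[["c1"]],
                             pars[["a2"]], pars[["b2"]], pars[["c2"]],
                             seed = 2000 + s, poisson = TRUE)
    fit <- fit_hue_gaussians(h)
    if (fit$n_peaks < 2L) return(Inf)
    # match fitted centroids to true ones irrespective of amplitude order
    max(min(abs(fit$b - pars[["b1"]])), min(abs(fit$b - pars[["b2"]])))
  })
  errs <- errs[!is.na(errs)]
  expect_gte(mean(errs <= 3), 0.95)
})

test_that("evaluate_fit follows the literal peak model", {
  h <- make_two_gauss_hist(5000, 40, 10, 2000, 120, 15)
  fit <- fit_hue_gaussians(h)
  # peak value and the 1/e point one width-parameter away
  expect_equal(evaluate_fit(fit, fit$b[1]),
               fit$a[1] + gauss_term_ref(fit$b[1], fit$a[2], fit$b[2],
                                         fit$c[2]),
               tolerance = 1e-9)
  one_term <- fit_hue_gaussians(make_two_gauss_hist(4000, 85, 12, 0, 0, 1))
  expect_equal(evaluate_fit(one_term, one_term$b[1] + one_term$c[1]),
               one_term$a[1] / exp(1), tolerance = 1e-9)
  # arbitrary points against an independent term-by-term sum
  xs <- c(0, 33.3, 80.1, 127.9, 200)
  ref <- gauss_term_ref(xs, fit$a[1], fit$b[1], fit$c[1]) +
    gauss_term_ref(xs, fit$a[2], fit$b[2], fit$c[2])
  expect_lt(max(abs(evaluate_fit(fit, xs) - ref)), 1e-12 * max(ref))
})

test_that("fitting requires a filtered histogram with enough bins", {
  unfiltered <- build_hue_histogram(matrix(runif(100, 0, 180), 10, 10))
  expect_error(fit_hue_gaussians(unfiltered), "filtered")
  small <- structure(list(bins = c(10L, 20L, 30L), counts = c(5, 9, 4),
                          total_pixels = 18L, filtered = TRUE),
                     class = "hue_histogram")
  expect_error(fit_hue_gaussians(small), "at least 4")
})
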