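# Single-peak fitting on power-law backgrounds and histogram condensation.

test_that("length-scale conversion follows the 2*pi/q convention", {
  expect_lt(abs(q_to_d(22) - 0.286), 5e-4)
  expect_lt(abs(q_to_d(4) - 1.57), 2e-3)
  expect_equal(q_to_d(2 * pi), 1)
  expect_equal(d_to_q(q_to_d(0.5)), 0.5)
  expect_error(q_to_d(0), "> 0")
  expect_error(q_to_d(-3), "> 0")
})

test_that("a noiseless Gaussian on a power-law background is recovered precisely", {
  q <- seq(2.5, 6, length.out = 400)
  I <- 120 * exp(-(q - 4.10)^2 / (2 * (0.6 / 2.3548)^2)) + 50 * q^(-1.5)
  prof <- qprofile(q, I, modality = "waxs")
  f <- fit_single_peak(prof, peak_window("waxs_equatorial"))
  expect_true(f$success)
  expect_lte(abs(f$q0 - 4.10), 0.01)
  expect_equal(f$fwhm_q, 0.6, tolerance = 0.02)
  expect_equal(f$d_spacing * f$q0, 2 * pi)
})

test_that("the third order of the 0.86 nm helix rise lands in the WAXS meridional window", {
  q0 <- 3 * 2 * pi / 0.86 # ~21.97 nm^-1
  q <- seq(19, 25, length.out = 400)
  I <- 80 * exp(-(q - q0)^2 / (2 * (1.2 / 2.3548)^2)) + 30 * q^(-0.8) + 2
  f <- fit_single_peak(qprofile(q, I, modality = "waxs"),
                       peak_window("waxs_meridional"))
  expect_true(f$success)
  expect_lte(abs(f$q0 - q0), 0.5 * f$fwhm_q)
  expect_equal(f$d_spacing, 0.86 / 3, tolerance = 0.005)
})

test_that("the ninth-order SAXS window translates 0.861 nm^-1 into a 7.30 nm spacing", {
  q <- seq(0.78, 0.97, length.out = 300)
  I <- 40 * exp(-(q - 0.861)^2 / (2 * 0.006^2)) + 5 * q^(-2)
  f <- fit_single_peak(qprofile(q, I), peak_window("saxs_meridional_9th"))
  expect_true(f$success)
  expect_equal(f$d_spacing, 7.30, tolerance = 0.02)
})

test_that("background-only windows are reported as unsuccessful, and bad windows error", {
  q <- seq(2.5, 6, length.out = 200)
  prof <- qprofile(q, 50 * q^(-1.5) + 2, modality = "waxs")
  f <- fit_single_peak(prof, peak_window("waxs_equatorial"))
  expect_false(f$success)
  expect_identical(f$amplitude, 0)
  expect_error(fit_single_peak(prof, peak_window("waxs_meridional")),
               "support")
  short <- qprofile(seq(2.5, 6, length.out = 10), rep(1, 10),
                    modality = "waxs")
  expect_error(fit_single_peak(short, peak_window("waxs_equatorial")),
               "15")
})

test_that("peak position estimates are unbiased within 5% of the FWHM under counting noise", {
  q <- seq(2.5, 6, length.out = 350)
  s <- 0.6 / 2.3548
  mu <- 300 * exp(-(q - 4.0)^2 / (2 * s^2)) + 100 * q^(-1.5) + 5
  win <- peak_window("waxs_equatorial")
  set.seed(42)
  q0s <- vapply(1:100, function(i) {
    prof <- qprofile(q, rpois(length(mu), mu), modality = "waxs")
    fit_single_peak(prof, win)$q0
  }, 0)
  expect_lt(abs(stats::median(q0s, na.rm = TRUE) - 4.0), 0.05 * 0.6)
})

test_that("scan-wide peak maps recover constancy and planted gradients", {
  qg <- seq(0.7, 1.1, length.out = 250)
  sp <- scan_spec(n_rows = 4, n_cols = 4, noise = "none", q_grid = qg)
  g <- generate_scan(sp)
  res <- scan_peaks(g, peak_window("saxs_meridional_9th"))
  expect_identical(nrow(res), 16L)
  expect_true(all(res$success))
  expect_lt(stats::sd(res$q0), 1e-9)
  # planted period gradient: q0 of the ninth order decreases as D grows
  # gradient kept narrow enough that only the ninth order lies in the window
  sp2 <- scan_spec(n_rows = 3, n_cols = 6, noise = "none", q_grid = qg,
                   parameter_maps = list(D = function(row, col) 63 + 0.4 * col))
  res2 <- scan_peaks(generate_scan(sp2), peak_window("saxs_meridional_9th"))
  m <- tapply(res2$q0, res2$col, mean)
  expect_true(all(diff(m) < 0))
})

test_that("histogram condensation selects the right mixture and weights by area", {
  set.seed(1)
  vals <- rnorm(4131, mean = 4.00, sd = 0.05)
  res <- data.frame(q0 = vals, success = TRUE)
  h <- summarize_histogram(res)
  expect_identical(h$n_components, 1L)
  expect_lt(abs(h$weighted_position - 4.00), 3 * 0.05 / sqrt(4131))
  # brute-force equivalence of the area weighting
  expect_equal(h$weighted_position,
               sum(h$components$weight * h$components$mean) /
                 sum(h$components$weight))
  expect_equal(h$weighted_fwhm,
               sum(h$components$weight * h$components$fwhm) /
                 sum(h$components$weight))
})

test_that("two equal-weight populations average to the midpoint", {
  set.seed(2)
  vals <- c(rnorm(2000, 3.9, 0.03), rnorm(2000, 4.1, 0.03))
  h <- summarize_histogram(data.frame(q0 = vals, success = TRUE))
  expect_identical(h$n_components, 2L)
  expect_equal(h$weighted_position, 4.0, tolerance = 0.01)
})

test_that("degenerate and undersized populations are handled explicitly", {
  h <- summarize_histogram(data.frame(q0 = rep(4, 100), success = TRUE))
  expect_identical(h$n_components, 1L)
  expect_equal(h$weighted_position, 4)
  expect_error(summarize_histogram(data.frame(q0 = rnorm(30, 4),
                                              success = TRUE)),
               "30")
})
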