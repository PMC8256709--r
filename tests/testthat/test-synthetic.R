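# Synthetic-data generator: determinism, noise statistics, scan assembly.

test_that("identical seeds give bit-identical profiles; different seeds differ", {
  tr <- ground_truth(seed = 5L)
  a <- generate_saxs_profile(tr)
  b <- generate_saxs_profile(tr)
  expect_identical(a$intensity, b$intensity)
  c2 <- generate_saxs_profile(tr, seed = 6L)
  expect_false(identical(a$intensity, c2$intensity))
  wa <- generate_waxs_profile(tr)
  wb <- generate_waxs_profile(tr)
  expect_identical(wa$intensity, wb$intensity)
})

test_that("noiseless output is non-negative and exactly reproducible", {
  tr <- ground_truth()
  a <- generate_saxs_profile(tr, noise = "none")
  expect_true(all(a$intensity >= 0))
  expect_identical(a$intensity,
                   generate_saxs_profile(tr, noise = "none")$intensity)
})

test_that("invalid q grids and negative peak amplitudes are rejected", {
  tr <- ground_truth()
  expect_error(generate_saxs_profile(tr, q_grid = c(-0.1, 0.2, 0.4)),
               "positive")
  expect_error(generate_saxs_profile(tr, q_grid = c(0.4, 0.2)),
               "increasing")
  expect_error(ground_truth(waxs_peaks = data.frame(q0 = 4, amplitude = -1,
                                                    fwhm = 0.5)),
               "negative")
})

test_that("odd orders 3 and 5 dominate the adjacent even order at sigma = 0.46", {
  prof <- generate_saxs_profile(ground_truth(), noise = "none")
  pk <- detect_bragg_peaks(prof)
  s <- 2 * pi / 65.5
  h <- function(n) pk$height[which.min(abs(pk$q - n * s))]
  expect_gt(h(3), h(4))
  expect_gt(h(5), h(4))
})

test_that("model peak positions agree with the FFT of the sampled step density within one grid step", {
  tr <- ground_truth()
  prof <- generate_saxs_profile(tr, noise = "none")
  pk <- detect_bragg_peaks(prof)
  dq <- diff(prof$q[1:2])
  # Bragg bins of the discrete transform sit exactly at 2*pi*n/D
  for (n in 3:9) {
    expect_lt(min(abs(pk$q - 2 * pi * n / tr$step$D)), dq)
  }
})

test_that("WAXS profiles peak at the planted positions and carry the power-law background", {
  tr <- ground_truth()
  prof <- generate_waxs_profile(tr, noise = "none")
  w1 <- prof$q >= 2.5 & prof$q <= 6
  w2 <- prof$q >= 19 & prof$q <= 25
  expect_equal(prof$q[w1][which.max(prof$intensity[w1])], 4.0,
               tolerance = 0.02)
  expect_equal(prof$q[w2][which.max(prof$intensity[w2])], 22.0,
               tolerance = 0.02)
})

test_that("Poisson sample mean converges to the noiseless expectation", {
  tr <- ground_truth()
  qg <- seq(0.2, 1.0, length.out = 40)
  mu <- generate_saxs_profile(tr, q_grid = qg, noise = "none")$intensity
  nrep <- 1000L
  acc <- matrix(0, nrep, length(qg))
  for (r in seq_len(nrep)) {
    acc[r, ] <- generate_saxs_profile(tr, q_grid = qg, seed = 1000L + r)$intensity
  }
  se <- sqrt(mu / nrep)
  z <- abs(colMeans(acc) - mu) / se
  expect_gte(mean(z <= 3), 0.99)
})

test_that("scan generation matches the raster geometry and per-pixel truth bookkeeping", {
  qg <- seq(0.2, 1.0, length.out = 60)
  sp <- scan_spec(n_rows = 81, n_cols = 51, q_grid = qg,
                  truth = ground_truth())
  g <- generate_scan(sp, seed = 3L)
  expect_identical(nrow(g$intensity), 4131L)
  expect_identical(nrow(g$index), 4131L)
  expect_equal(max(g$index$x_um), 50 * 50)
  # determinism of the whole scan
  g2 <- generate_scan(sp, seed = 3L)
  expect_identical(g$intensity, g2$intensity)
})

test_that("a constant-truth noiseless grid contains identical profiles everywhere", {
  sp <- scan_spec(n_rows = 4, n_cols = 4, noise = "none",
                  q_grid = seq(0.1, 1.1, length.out = 80))
  g <- generate_scan(sp)
  expect_identical(nrow(g$intensity), 16L)
  for (i in 2:16) expect_identical(g$intensity[i, ], g$intensity[1, ])
})

test_that("outlier regions must lie inside the grid and override the local truth", {
  out_tr <- ground_truth(step = default_truth_params(D = 60))
  expect_error(scan_spec(n_rows = 4, n_cols = 4,
                         outlier_regions = list(list(rows = 3:6, cols = 1:2,
                                                     truth = out_tr))),
               "outside")
  sp <- scan_spec(n_rows = 4, n_cols = 4, noise = "none",
                  q_grid = seq(0.1, 1.1, length.out = 80),
                  outlier_regions = list(list(rows = 2, cols = 2,
                                              truth = out_tr)))
  g <- generate_scan(sp)
  expect_equal(g$truths[[which(g$index$row == 2 & g$index$col == 2)]]$step$D, 60)
  expect_equal(g$truths[[1]]$step$D, 65.5)
})

test_that("smooth parameter maps impose the requested lateral gradient", {
  sp <- scan_spec(n_rows = 3, n_cols = 5, noise = "none",
                  q_grid = seq(0.1, 1.1, length.out = 120),
                  parameter_maps = list(D = function(row, col) 63 + 0.5 * col))
  g <- generate_scan(sp)
  d_vals <- vapply(g$truths, function(t) t$step$D, 0)
  expect_equal(sort(unique(d_vals)), 63 + 0.5 * (1:5))
})
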