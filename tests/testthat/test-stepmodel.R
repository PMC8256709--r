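# Forward model: finite-grating interference, two-level cell diffraction
# term, Lorentzian damping and their product.

test_that("interference term equals N^2 at the Bragg condition and 1 for N = 1", {
  D <- 65.5
  for (n in 1:6) {
    expect_identical(interference_term(2 * pi * n / D, D, 10L), 100)
  }
  q <- seq(0.05, 1.2, length.out = 101)
  expect_equal(interference_term(q, D, 1L), rep(1, length(q)))
})

test_that("interference term matches the direct geometric-sum oracle off the Bragg condition", {
  D <- 65.5
  N <- 10L
  q <- 2 * pi * (3:8 + 0.5) / D # midway between orders
  oracle <- vapply(q, function(qq) {
    Mod(sum(exp(1i * qq * (0:(N - 1)) * D)))^2
  }, 0)
  expect_lt(max(oracle), 1) # midway values are tiny for N = 10
  expect_equal(interference_term(q, D, N), oracle, tolerance = 1e-10)
})

test_that("peak width of the interference term scales as 1/N", {
  D <- 65.5
  q <- seq(0.28, 0.295, length.out = 6000)
  fw <- vapply(c(5L, 10L, 20L), function(N) {
    numeric_fwhm(q, interference_term(q, D, N))
  }, 0)
  expect_equal(fw[1] / fw[2], 2, tolerance = 0.05)
  expect_equal(fw[2] / fw[3], 2, tolerance = 0.05)
})

test_that("even diffraction orders vanish for the symmetric density and the fluctuation term matches its Bragg closed form", {
  D <- 65.5
  for (n in c(2, 4, 6, 8)) {
    qn <- 2 * pi * n / D
    expect_equal(diffraction_term(qn, D, sigma = 0.5, delta_rho = 0.08,
                                  component = "fluctuation"),
                 0, tolerance = 1e-20)
  }
  # general sigma: fluctuation at q_n = 4 drho^2 sin^2(pi n sigma) / q_n^2
  sigma <- 0.46
  drho <- 0.08
  for (n in 1:9) {
    qn <- 2 * pi * n / D
    expect_equal(diffraction_term(qn, D, sigma, delta_rho = drho,
                                  component = "fluctuation"),
                 4 * drho^2 * sin(pi * n * sigma)^2 / qn^2,
                 tolerance = 1e-10)
  }
})

test_that("zero contrast leaves only the monotone 1/q^2 decay", {
  q <- seq(0.1, 1.2, length.out = 300)
  tot <- diffraction_term(q, 65.5, 0.46, rho_ave = 1, delta_rho = 0)
  expect_equal(tot, 4 / q^2, tolerance = 1e-12)
  expect_error(diffraction_term(c(0, 0.1), 65.5, 0.46), "excluded")
})

test_that("Bragg-order weights match a Fourier-series oracle of the sampled step density", {
  sigma <- 0.46
  D <- 65.5
  N <- 10L
  drho <- 0.08
  n <- 1:9
  qn <- 2 * pi * n / D
  model <- diffraction_term(qn, D, sigma, rho_ave = 0, delta_rho = drho,
                            component = "fluctuation") *
    interference_term(qn, D, N)
  oracle <- fft_bragg_intensities(D, N, sigma, drho)
  expect_equal(model / model[3], oracle / oracle[3], tolerance = 0.01)
})

test_that("damping is 1 when disabled, monotone, and approaches its floor", {
  q <- seq(0.05, 30, length.out = 500)
  expect_equal(damping(q, w = 0, c = 0), rep(1, length(q)))
  expect_equal(damping(q, w = 9, c = 1), rep(1, length(q)))
  d <- damping(q, w = 9, c = 0.05)
  expect_true(all(diff(d) <= 0))
  expect_equal(damping(0, w = 9, c = 0.05), 1)
  # asymptote: within 0.25% of the floor by 20 Lorentzian widths, within
  # 1% relative by 60 widths
  expect_lt(abs(damping(20 * 2 * pi / 9, 9, 0.05) - 0.05), 0.0025)
  expect_lt(abs(damping(60 * 2 * pi / 9, 9, 0.05) / 0.05 - 1), 0.01)
})

test_that("forward intensity is non-negative, peaks at Bragg positions, and orders according to sin^2(pi n sigma)", {
  q <- default_saxs_q()
  p <- default_truth_params()
  I <- forward_intensity(q, p)
  expect_true(all(I >= 0))
  prof <- qprofile(q, I)
  pk <- detect_bragg_peaks(prof)
  s <- 2 * pi / p$D
  grating_fwhm <- 0.886 * 2 * pi / (p$N * p$D)
  for (n in 3:9) {
    expect_lt(min(abs(pk$q - n * s)), grating_fwhm / 2)
  }
  h <- function(n) pk$height[which.min(abs(pk$q - n * s))]
  expect_lt(h(4), h(3))
  expect_lt(h(4), h(5))
  # no interference peaks without contrast
  I0 <- forward_intensity(q, default_truth_params(delta_rho = 0))
  expect_equal(I0, 4 / q^2, tolerance = 1e-12)
  expect_error(forward_intensity(numeric(0), p), "empty")
})
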