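# Independent oracles and shared fixtures for the test suite.

default_truth_params <- function(...) {
  args <- utils::modifyList(list(D = 65.5, N = 10L, sigma = 0.46,
                                 rho_ave = 1, delta_rho = 0.08,
                                 w = 9, c = 0.05), list(...))
  do.call(step_params, args)
}

# Brute-force Fourier oracle: sample the N-period two-level density on a
# fine grid, take the discrete Fourier transform, and read |F|^2 at the
# Bragg bins (order n sits at DFT index n*N). Independent of the
# closed-form model.
fft_bragg_intensities <- function(D, N, sigma, delta_rho, rho_ave = 0,
                                  m_per_period = 10000, n_orders = 9) {
  M <- N * m_per_period
  xfrac <- ((seq_len(M) - 0.5) / m_per_period) %% 1
  rho <- ifelse(xfrac < sigma, rho_ave + delta_rho, rho_ave - delta_rho)
  I <- Mod(stats::fft(rho))^2
  vapply(seq_len(n_orders), function(n) I[n * N + 1], 0)
}

# Closed-form Bragg-order weights of the damped step-density model:
# I_n proportional to damping(q_n) * sin^2(pi n sigma) / n^2.
closed_form_asymmetry <- function(sigma, D = 65.5, w = 9, c = 0.05,
                                  max_order = 9) {
  n <- 3:max_order
  qn <- 2 * pi * n / D
  wts <- damping(qn, w, c) * sin(pi * n * sigma)^2 / n^2
  sum(wts[n %% 2 == 0]) / sum(wts[n %% 2 == 1])
}

# Synthetic "comb" profile: Gaussian peaks of equal width centred exactly
# on lattice positions q_n = 2*pi*n/D that coincide with grid points, on a
# flat background. Used for machine-precision indexing checks.
comb_profile <- function(D = 65, orders = 3:9, heights = NULL,
                         oversample = 24L, peak_points = 4) {
  s <- 2 * pi / D
  dq <- s / oversample
  q <- seq(dq * round(0.18 / dq), dq * round(1.04 / dq), by = dq)
  if (is.null(heights)) heights <- 100 / orders
  I <- rep(1, length(q))
  for (i in seq_along(orders)) {
    q0 <- s * orders[i]
    width <- peak_points * dq / 2.3548
    I <- I + heights[i] * exp(-(q - q0)^2 / (2 * width^2))
  }
  qprofile(q, I, modality = "saxs")
}

# numeric FWHM of a curve y(x) around its maximum, by linear interpolation
numeric_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  l <- i; while (l > 1 && y[l] > half) l <- l - 1
  r <- i; while (r < length(y) && y[r] > half) r <- r + 1
  xl <- x[l] + (x[l + 1] - x[l]) * (half - y[l]) / (y[l + 1] - y[l])
  xr <- x[r - 1] + (x[r] - x[r - 1]) * (half - y[r - 1]) / (y[r] - y[r - 1])
  xr - xl
}
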