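# Single-peak analysis at the four characteristic collagen length scales,
# and per-sample condensation of per-pixel peak positions into weighted
# histogram summaries.

.default_windows <- list(
  waxs_equatorial      = list(q_range = c(2.5, 6.0),  nominal_d = 1.5),
  waxs_meridional      = list(q_range = c(19, 25),    nominal_d = 0.286),
  saxs_meridional_9th  = list(q_range = c(0.80, 0.95), nominal_d = 7.2),
  saxs_equatorial_fibril = list(q_range = c(0.03, 0.08), nominal_d = 125)
)

#' Peak-analysis window
#'
#' A named q window isolating one of the four characteristic collagen
#' features: the ~1.5 nm lateral triple-helix spacing (WAXS equatorial,
#' q in 2.5-6 nm^-1), the ~0.286 nm axial residue rise (WAXS meridional,
#' 19-25 nm^-1), the ninth order of the ~65 nm axial period (SAXS
#' meridional, 0.80-0.95 nm^-1, d = 7.16-7.3 nm) and the 100-150 nm fibril
#' diameter (SAXS equatorial, 0.03-0.08 nm^-1, inter-fibril 2*pi/q
#' convention).
#'
#' @param name One of `"waxs_equatorial"`, `"waxs_meridional"`,
#'   `"saxs_meridional_9th"`, `"saxs_equatorial_fibril"`; or any name when
#'   `q_range` is supplied explicitly.
#' @param q_range Optional `c(q_lo, q_hi)` override (nm^-1).
#' @param nominal_d Optional expected length scale (nm); must satisfy
#'   `2*pi/q_hi <= nominal_d <= 2*pi/q_lo`.
#' @return An object of class `peak_window`.
#' @export
peak_window <- function(name, q_range = NULL, nominal_d = NULL) {
  if (is.null(q_range)) {
    if (!name %in% names(.default_windows)) {
      stop("unknown window name; supply q_range or use one of: ",
           paste(names(.default_windows), collapse = ", "))
    }
    def <- .default_windows[[name]]
    q_range <- def$q_range
    if (is.null(nominal_d)) nominal_d <- def$nominal_d
  }
  if (q_range[1] >= q_range[2] || q_range[1] <= 0) {
    stop("need 0 < q_lo < q_hi")
  }
  if (!is.null(nominal_d) &&
      (nominal_d < 2 * pi / q_range[2] - 1e-9 ||
       nominal_d > 2 * pi / q_range[1] + 1e-9)) {
    stop("nominal_d inconsistent with 2*pi/q inside the window")
  }
  structure(list(name = name, q_range = q_range, nominal_d = nominal_d),
            class = "peak_window")
}

#' Fit a single Gaussian peak on a power-law background
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of
#' `amp * exp(-(q - q0)^2 / (2 s^2)) + A * q^-n + floor`
#' to the profile restricted to the window. The additive constant floor
#' (detector/dark level) extends the plain `q^-n` background. The fit is
#' flagged unsuccessful when the fitted amplitude is below three times the
#' residual RMSE, when `q0` leaves the window, or when the optimiser fails
#' (a background-only result is then returned).
#'
#' @param profile A [qprofile].
#' @param window A [peak_window] lying within the profile's q support with
#'   at least 15 data points inside.
#' @return An object of class `peak_fit`: `q0`, `amplitude`, `fwhm_q`,
#'   `background` (A, n, floor), `d_spacing = 2*pi/q0`, `success`, `rmse`.
#' @examples
#' tr <- ground_truth()
#' p <- generate_waxs_profile(tr, noise = "none")
#' fit_single_peak(p, peak_window("waxs_equatorial"))
#' @export
fit_single_peak <- function(profile, window) {
  stopifnot(inherits(profile, "qprofile"), inherits(window, "peak_window"))
  if (window$q_range[1] < min(profile$q) - 1e-9 ||
      window$q_range[2] > max(profile$q) + 1e-9) {
    stop("window outside the profile's q support")
  }
  sel <- profile$q >= window$q_range[1] & profile$q <= window$q_range[2]
  q <- profile$q[sel]
  I <- profile$intensity[sel]
  if (length(q) < 15) stop("fewer than 15 data points inside the window")

  # starting values: background slope from averaged window edges, peak
  # position and width from the smoothed residual
  ne <- max(3L, length(q) %/% 12)
  I1 <- mean(I[seq_len(ne)]); q1 <- mean(q[seq_len(ne)])
  I2 <- mean(I[length(I) - seq_len(ne) + 1L])
  q2 <- mean(q[length(q) - seq_len(ne) + 1L])
  n0 <- log(max(I1, 1e-9) / max(I2, 1e-9)) / log(q2 / q1)
  n0 <- min(max(n0, 0), 6)
  floor0 <- max(min(I), 0) * 0.5
  A0 <- max((I1 - floor0) * q1^n0, 1e-9)
  bg0 <- A0 * q^(-n0) + floor0
  resid0 <- I - bg0
  # locate the peak against a running-median baseline (robust to
  # curvature the two-point power-law estimate misses)
  k <- length(I) %/% 2
  if (k %% 2 == 0) k <- k - 1L
  k <- max(7L, k)
  base <- stats::runmed(I, k)
  sm <- as.numeric(stats::filter(I, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- I[is.na(sm)]
  detr <- sm - base
  j <- which.max(detr)
  half <- detr[j] / 2
  l <- j; while (l > 1 && detr[l] > half) l <- l - 1
  r <- j; while (r < length(detr) && detr[r] > half) r <- r + 1
  s0 <- max((q[r] - q[l]) / 2.3548, 1.5 * stats::median(diff(q)))
  start <- list(amp = max(detr[j], 1e-6), q0 = q[j],
                s = min(s0, diff(window$q_range) / 4), A = A0, n = n0,
                floor = floor0)

  # Levenberg-Marquardt on the explicit residual (minpack.lm::nls.lm):
  # more robust than the formula interface on noiseless/near-degenerate
  # windows
  peak_resid <- function(par) {
    I - (par[1] * exp(-(q - par[2])^2 / (2 * par[3]^2)) +
           par[4] * q^(-par[5]) + par[6])
  }
  bg_resid <- function(par) I - (par[1] * q^(-par[2]) + par[3])

  bg_result <- function() {
    bgfit <- tryCatch(
      minpack.lm::nls.lm(par = c(A = A0, n = n0, floor = floor0),
                         fn = bg_resid,
                         lower = c(0, 0, 0), upper = c(Inf, 6, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(bgfit)) {
      bg <- c(A = A0, n = n0, floor = floor0)
      rmse <- sqrt(mean(resid0^2))
    } else {
      bg <- bgfit$par
      rmse <- sqrt(mean(bgfit$fvec^2))
    }
    structure(list(q0 = NA_real_, amplitude = 0, fwhm_q = NA_real_,
                   background = bg, d_spacing = NA_real_,
                   success = FALSE, rmse = rmse, window = window$name),
              class = "peak_fit")
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start),
      fn = peak_resid,
      lower = c(0, window$q_range[1], 1e-6, 0, 0, 0),
      upper = c(Inf, window$q_range[2], diff(window$q_range), Inf, 6, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info <= 0) return(bg_result())

  co <- fit$par
  rmse <- sqrt(mean(fit$fvec^2))
  success <- is.finite(co[["amp"]]) && co[["amp"]] >= 3 * rmse &&
    co[["amp"]] > 1e-6 * max(I) && # amplitude consistent with zero
    co[["q0"]] > window$q_range[1] + 1e-9 &&
    co[["q0"]] < window$q_range[2] - 1e-9
  if (!success) return(bg_result())
  structure(list(q0 = co[["q0"]],
                 amplitude = co[["amp"]],
                 fwhm_q = 2 * sqrt(2 * log(2)) * co[["s"]],
                 background = c(A = co[["A"]], n = co[["n"]],
                                floor = co[["floor"]]),
                 d_spacing = 2 * pi / co[["q0"]],
                 success = TRUE, rmse = rmse, window = window$name),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (x$success) {
    cat(sprintf("<peak_fit> [%s] q0 = %.4f nm^-1 (d = %.4f nm), amp = %.3g, FWHM = %.4f\n",
                x$window, x$q0, x$d_spacing, x$amplitude, x$fwhm_q))
  } else {
    cat(sprintf("<peak_fit> [%s] no significant peak (background only)\n",
                x$window))
  }
  invisible(x)
}

#' Fit one peak window across every pixel of a scan
#'
#' Runs [fit_single_peak()] on every frame of the scan; per-pixel failures
#' are recorded (success = FALSE), never dropped.
#'
#' @param grid A [scan_grid].
#' @param window A [peak_window].
#' @return A data frame with one row per pixel: `row`, `col`, `q0`, `d_nm`,
#'   `amplitude`, `fwhm_q`, `success`, `rmse`.
#' @export
scan_peaks <- function(grid, window) {
  stopifnot(inherits(grid, "scan_grid"))
  npx <- nrow(grid$intensity)
  out <- grid$index[, c("row", "col")]
  out$q0 <- out$d_nm <- out$amplitude <- out$fwhm_q <- NA_real_
  out$success <- FALSE
  out$rmse <- NA_real_
  for (i in seq_len(npx)) {
    f <- tryCatch(fit_single_peak(get_profile(grid, i), window),
                  error = function(e) NULL)
    if (is.null(f)) next
    out$q0[i] <- f$q0
    out$d_nm[i] <- f$d_spacing
    out$amplitude[i] <- f$amplitude
    out$fwhm_q[i] <- f$fwhm_q
    out$success[i] <- f$success
    out$rmse[i] <- f$rmse
  }
  out
}

#' Condense per-pixel peak positions into a histogram summary
#'
#' The population of successful per-pixel peak positions is modelled by a
#' Gaussian mixture with 1 to `max_components` components; the component
#' count is selected by BIC. The sample's characteristic peak position is
#' the component means weighted by the area (mixing proportion) of each
#' component, and the characteristic FWHM is the component FWHMs weighted
#' identically; that FWHM serves as the uncertainty of the length-scale
#' estimate. Histogram bin edges (Freedman-Diaconis) are returned for
#' plotting.
#'
#' @param results A [scan_peaks()] data frame (or any data frame with
#'   columns `q0` and `success`).
#' @param max_components Maximum number of mixture components (default 3).
#' @param min_success Minimum number of successful fits required
#'   (default 50).
#' @return An object of class `histogram_summary`: `values`, `bin_edges`,
#'   `components` (data frame `weight`, `mean`, `fwhm`),
#'   `weighted_position`, `weighted_fwhm`, `weighted_d` (2*pi over the
#'   weighted position), `n_components`, `n_values`.
#' @export
summarize_histogram <- function(results, max_components = 3L,
                                min_success = 50L) {
  vals <- results$q0[results$success]
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_success) {
    stop(sprintf("only %d successful fits (need >= %d)",
                 length(vals), min_success))
  }
  bin_edges <- graphics::hist(vals, breaks = "FD", plot = FALSE)$breaks
  if (stats::sd(vals) < 1e-12) {
    # degenerate population: one component at the common value
    comp <- data.frame(weight = 1, mean = vals[1],
                       fwhm = diff(bin_edges[1:2]))
  } else {
    mc <- mclust::Mclust(vals, G = seq_len(max_components),
                         modelNames = "V", verbose = FALSE)
    if (is.null(mc)) stop("mixture fit failed")
    par <- mc$parameters
    comp <- data.frame(weight = par$pro,
                       mean = as.numeric(par$mean),
                       fwhm = 2 * sqrt(2 * log(2)) *
                         sqrt(as.numeric(par$variance$sigmasq)))
    if (length(par$variance$sigmasq) == 1 && nrow(comp) > 1) {
      comp$fwhm <- comp$fwhm[1]
    }
    comp <- comp[order(comp$mean), , drop = FALSE]
  }
  wpos <- sum(comp$weight * comp$mean) / sum(comp$weight)
  wfwhm <- sum(comp$weight * comp$fwhm) / sum(comp$weight)
  structure(list(values = vals, bin_edges = bin_edges, components = comp,
                 weighted_position = wpos, weighted_fwhm = wfwhm,
                 weighted_d = 2 * pi / wpos,
                 n_components = nrow(comp), n_values = length(vals)),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf(paste0("<histogram_summary> %d values, %d component(s); ",
                     "weighted position %.4f nm^-1 (d = %.4f nm), ",
                     "weighted FWHM %.4f\n"),
              x$n_values, x$n_components, x$weighted_position,
              x$weighted_d, x$weighted_fwhm))
  invisible(x)
}
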