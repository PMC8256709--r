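# Staged coordinate-descent fit of the two-level step-density model.
#
# The error function is the unweighted sum of squares between data and
# model over the fit range; the overall intensity scale K is an auxiliary
# linear parameter solved in closed form at every evaluation (profiles are
# in arbitrary units).

.fit_error <- function(q, I, p) {
  m <- forward_intensity(q, p)
  K <- sum(I * m) / sum(m * m)
  if (!is.finite(K) || K < 0) K <- 0
  r <- I - K * m
  list(sse = sum(r * r), K = K)
}

# One-dimensional descent along a parameter grid: step in one direction
# while the error strictly decreases, then try the other direction. Equal
# error keeps the smaller-magnitude change (bias toward the current value).
.search_param <- function(q, I, p, field, step, lower, upper, best_sse) {
  for (dir in c(1, -1)) {
    repeat {
      val <- p[[field]] + dir * step
      if (val < lower - 1e-12 || val > upper + 1e-12) break
      cand <- p
      cand[[field]] <- min(max(val, lower), upper)
      sse <- .fit_error(q, I, cand)$sse
      if (sse < best_sse * (1 - 1e-12)) {
        p <- cand
        best_sse <- sse
      } else {
        break
      }
    }
  }
  list(p = p, sse = best_sse)
}

# One full staged descent at fixed N: stages (i)-(iii) alternate the
# contrast and damping line searches until stable, stage (iv) refines D
# and sigma, and the cycle repeats until the error stops decreasing or
# max_iter outer iterations are reached.
.descend <- function(q, I, p, max_iter, steps) {
  best <- .fit_error(q, I, p)$sse
  n_it <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_it <- it
    e_outer <- best
    repeat {
      e_in <- best
      r <- .search_param(q, I, p, "delta_rho", steps$delta_rho, 0, Inf, best)
      p <- r$p; best <- r$sse
      repeat {
        e_d <- best
        r <- .search_param(q, I, p, "w", steps$w, 0, Inf, best)
        p <- r$p; best <- r$sse
        r <- .search_param(q, I, p, "c", steps$c, 0, 1, best)
        p <- r$p; best <- r$sse
        if (best >= e_d * (1 - 1e-10)) break
      }
      if (best >= e_in * (1 - 1e-10)) break
    }
    r <- .search_param(q, I, p, "D", steps$D, 1, Inf, best)
    p <- r$p; best <- r$sse
    r <- .search_param(q, I, p, "sigma", steps$sigma, 1e-3, 1 - 1e-3, best)
    p <- r$p; best <- r$sse
    if (best >= e_outer * (1 - 1e-8)) {
      converged <- TRUE
      break
    }
  }
  list(p = p, best = best, n_it = n_it, converged = converged)
}

# Initial parameter values from detected Bragg peaks: D from the regression
# of peak position vs assigned order, N from the peak FWHM via the
# finite-grating main-lobe width FWHM_q = 0.886 * 2*pi / (N * D),
# sigma = 0.46 (nominal overlap fraction of hydrated collagen), rho_ave = 1,
# delta_rho = 0 and no damping (w = c = 0).
.init_step_params <- function(peaks, sigma0 = 0.46) {
  idx <- .assign_orders(peaks)
  D <- idx$D_est
  n_est <- 0.886 * 2 * pi / (D * peaks$fwhm[idx$keep])
  N <- round(stats::median(n_est, na.rm = TRUE))
  N <- min(max(N, 3L), 30L)
  step_params(D = D, N = N, sigma = sigma0, rho_ave = 1, delta_rho = 0,
              w = 0, c = 0)
}

#' Fit the step-density model to a meridional SAXS profile
#'
#' Staged coordinate-descent least-squares fit of [forward_intensity()] to
#' a measured (or synthetic) profile. Initial values: the period `D` from
#' the positions of the higher-order Bragg peaks, `N` from their FWHM,
#' `sigma = 0.46`, `rho_ave = 1`, `delta_rho = 0` and unit damping
#' (`w = c = 0`). The routine then minimises the least squares by (i)
#' stepping `delta_rho` in increments of 0.001, (ii) stepping the damping
#' parameters `w` (0.1 nm) and `c` (0.01), (iii) alternating (i) and (ii)
#' until no further improvement, (iv) refining `D` (0.1 nm steps) and
#' `sigma` (0.001 steps), and (v) repeating the whole cycle until the error
#' stops decreasing, for at most `max_iter` outer iterations (default 10).
#' Data before the first scattering peak are excluded from the fit range.
#'
#' @param profile A [qprofile] covering at least three Bragg orders.
#' @param init Optional [step_params] overriding the automatic
#'   initialisation.
#' @param fit_range Optional `c(q_min, q_max)` actually used in the error
#'   function; default: from just below the first detected peak to the end
#'   of the profile.
#' @param max_iter Maximum number of outer iterations (default 10).
#' @param steps Named list of grid steps
#'   (`delta_rho`, `w`, `c`, `D`, `sigma`).
#' @param sigma0 Starting overlap fraction (default 0.46).
#' @param refine_N Select the integer period count `N` by the best full
#'   fit over neighbouring candidates of the FWHM-based estimate (the
#'   comparison with the model is more sensitive to the peak width than
#'   the direct FWHM measurement under counting noise). `FALSE` keeps the
#'   initial estimate.
#' @return An object of class `step_fit`: `params` (fitted [step_params]),
#'   `scale` (fitted overall intensity scale K), `r_squared`, `rmse`,
#'   `n_iterations`, `fit_range`, `converged`, `init` (the initialisation
#'   used).
#' @examples
#' q <- seq(0.06, 1.15, length.out = 800)
#' truth <- step_params(D = 65.5, N = 10, sigma = 0.46, delta_rho = 0.08,
#'                      w = 9, c = 0.05)
#' prof <- qprofile(q, forward_intensity(q, truth, scale = 1e4))
#' fit <- fit_profile(prof)
#' fit$params$D
#' @export
fit_profile <- function(profile, init = NULL, fit_range = NULL,
                        max_iter = 10L,
                        steps = list(delta_rho = 0.001, w = 0.1, c = 0.01,
                                     D = 0.1, sigma = 0.001),
                        sigma0 = 0.46, refine_N = TRUE) {
  stopifnot(inherits(profile, "qprofile"))
  peaks <- tryCatch(detect_bragg_peaks(profile),
                    error = function(e) data.frame(q = numeric(0)))
  if (is.null(init)) {
    if (nrow(peaks) < 2) {
      stop("insufficient orders: fewer than 2 Bragg peaks detected")
    }
    init <- .init_step_params(peaks, sigma0 = sigma0)
  }
  if (is.null(fit_range)) {
    fit_range <- if (nrow(peaks) >= 1) {
      c(peaks$q[1] - peaks$fwhm[1], max(profile$q))
    } else {
      range(profile$q)
    }
  }
  sel <- profile$q >= fit_range[1] & profile$q <= fit_range[2]
  q <- profile$q[sel]
  I <- profile$intensity[sel]
  if (length(q) < 20) stop("fit range contains too few points")

  res <- .descend(q, I, init, max_iter, steps)
  if (refine_N) {
    # N enters through both peak height (N^2) and width (1/N); it is
    # selected by the best full fit over integer candidates, walking away
    # from the FWHM-based estimate while the error keeps decreasing
    for (dir in c(1L, -1L)) {
      repeat {
        N_try <- res$p$N + dir
        if (N_try < 1L) break
        init2 <- init
        init2$N <- N_try
        cand <- .descend(q, I, init2, max_iter, steps)
        if (cand$best < res$best * (1 - 1e-10)) res <- cand else break
      }
    }
  }
  p <- res$p
  n_it <- res$n_it
  converged <- res$converged
  fe <- .fit_error(q, I, p)
  ss_tot <- sum((I - mean(I))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - fe$sse / ss_tot)) else NA_real_
  structure(list(params = p, scale = fe$K,
                 r_squared = r2,
                 rmse = sqrt(fe$sse / length(q)),
                 n_iterations = n_it,
                 fit_range = fit_range,
                 converged = converged,
                 init = init),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> R^2 = %.4f, RMSE = %.4g, %d iteration(s)%s\n",
              x$r_squared, x$rmse, x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$params)
  invisible(x)
}

#' RMSE landscape over the overlap fraction
#'
#' Recomputes the root-mean-square error between data and model as the
#' overlap fraction `sigma` is varied over a grid while every other fitted
#' parameter (period, contrast, damping, scale) is held constant. Reported
#' against the gap fraction `1 - sigma`. The landscape is exactly symmetric
#' under `sigma <-> 1 - sigma` (Babinet ambiguity of the two-level
#' density), so the minimum is a degenerate pair.
#'
#' @param profile The [qprofile] that was fitted.
#' @param fitted A [fit_profile()] result.
#' @param sigma_grid Overlap fractions to evaluate, all in (0, 1).
#' @return An object of class `sigma_landscape`: a data frame with columns
#'   `sigma`, `gap_fraction`, `rmse`.
#' @seealso [landscape_minimum()]
#' @export
sigma_landscape <- function(profile, fitted,
                            sigma_grid = seq(0.3, 0.7, by = 0.005)) {
  stopifnot(inherits(profile, "qprofile"), inherits(fitted, "step_fit"))
  if (any(sigma_grid <= 0) || any(sigma_grid >= 1)) {
    stop("sigma_grid must lie strictly inside (0, 1)")
  }
  sel <- profile$q >= fitted$fit_range[1] & profile$q <= fitted$fit_range[2]
  q <- profile$q[sel]
  I <- profile$intensity[sel]
  rmse <- vapply(sigma_grid, function(s) {
    p <- fitted$params
    p$sigma <- s
    m <- forward_intensity(q, p, scale = fitted$scale)
    sqrt(mean((I - m)^2))
  }, 0)
  structure(data.frame(sigma = sigma_grid,
                       gap_fraction = 1 - sigma_grid,
                       rmse = rmse),
            class = c("sigma_landscape", "data.frame"))
}

#' Gap fraction at the landscape minimum
#'
#' Returns the gap fraction `1 - sigma` at the global minimum of a
#' [sigma_landscape()]. Because the landscape is exactly Babinet-symmetric,
#' the global minimum is generally a tie between a gap fraction and its
#' complement; ties (within `tol` relative error) are broken toward the gap
#' fraction > 0.5, the physical convention for hydrated collagen (gap
#' 0.54 D, overlap 0.46 D).
#'
#' @param landscape A [sigma_landscape()] result.
#' @param tol Relative RMSE tolerance within which minima count as tied.
#' @return The gap fraction (scalar) at the minimum.
#' @export
landscape_minimum <- function(landscape, tol = 1e-9) {
  stopifnot(inherits(landscape, "sigma_landscape"))
  m <- min(landscape$rmse)
  tied <- landscape$rmse <= m * (1 + tol)
  gf <- landscape$gap_fraction[tied]
  r <- landscape$rmse[tied]
  if (any(gf > 0.5)) {
    gf[gf > 0.5][which.min(r[gf > 0.5])]
  } else {
    gf[which.min(r)]
  }
}

#' @export
plot.sigma_landscape <- function(x, ...) {
  ord <- order(x$gap_fraction)
  graphics::plot(x$gap_fraction[ord], x$rmse[ord], type = "l",
                 xlab = expression(gap ~ fraction ~ (1 - sigma)),
                 ylab = "RMSE", ...)
  invisible(x)
}
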