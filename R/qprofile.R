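#' One-dimensional scattering profile
#'
#' A `qprofile` holds one azimuthally averaged 1D scattering curve: the
#' scattering-vector grid `q` (nm^-1), the intensity (counts, arbitrary
#' units) and an optional per-point uncertainty. The `modality` tag records
#' whether the curve covers the SAXS (above-molecular, ~5-200 nm) or WAXS
#' (sub-molecular, ~0.2-2 nm) regime.
#'
#' @param q Numeric vector of scattering-vector magnitudes (nm^-1), strictly
#'   increasing and positive.
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of 1-sigma uncertainties.
#' @param modality `"saxs"` or `"waxs"`.
#' @return An object of class `qprofile` (a list with elements `q`,
#'   `intensity`, `sigma`, `modality`).
#' @examples
#' p <- qprofile(q = seq(0.1, 1, length.out = 50), intensity = rep(1, 50))
#' q_to_d(p$q[1])
#' @export
qprofile <- function(q, intensity, sigma = NULL, modality = c("saxs", "waxs")) {
  modality <- match.arg(modality)
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) == 0L) stop("empty q grid")
  if (length(q) != length(intensity)) {
    stop("q and intensity must have the same length")
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("q must be finite and strictly positive")
  }
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma must match q in length")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 modality = modality),
            class = "qprofile")
}

#' @export
print.qprofile <- function(x, ...) {
  cat(sprintf("<qprofile> %s, %d points, q in [%.4g, %.4g] nm^-1\n",
              toupper(x$modality), length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.qprofile <- function(x, log = "y", ...) {
  graphics::plot(x$q, pmax(x$intensity, .Machine$double.eps),
                 type = "l", log = log,
                 xlab = expression(q ~ (nm^-1)), ylab = "intensity", ...)
  invisible(x)
}

#' Convert between scattering vector and real-space length scale
#'
#' Length scales are reported with the inter-planar convention d = 2*pi/q
#' (so the meridional WAXS peak at q = 22 nm^-1 corresponds to the ~0.286 nm
#' axial residue spacing, and the equatorial peak at q = 4 nm^-1 to the
#' ~1.57 nm lateral triple-helix spacing).
#'
#' @param q Scattering-vector magnitude(s), nm^-1; must be > 0.
#' @param d Length scale(s), nm; must be > 0.
#' @return `q_to_d` returns d = 2*pi/q in nm; `d_to_q` the inverse.
#' @examples
#' q_to_d(22)   # ~0.286 nm
#' q_to_d(4)    # ~1.57 nm
#' @export
q_to_d <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be > 0")
  2 * pi / q
}

#' @rdname q_to_d
#' @export
d_to_q <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be > 0")
  2 * pi / d
}

#' Average profile of a scan grid
#'
#' Pixel-wise mean intensity across all frames of a scan, on the common q
#' grid. This is the "average SAXS profile per sample" on which the period
#' fit and the asymmetry value are computed.
#'
#' @param grid A [scan_grid] object.
#' @return A [qprofile].
#' @export
average_profile <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  qprofile(grid$q, colMeans(grid$intensity), modality = grid$modality)
}
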