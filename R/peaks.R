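#' Detect meridional Bragg peaks in a SAXS profile
#'
#' Peak detection used to initialise the step-density fit and to index
#' diffraction orders. The intensity is weighted by q^2 (which flattens the
#' monotone mean-density decay), lightly smoothed, and a running-median
#' baseline is subtracted; local maxima of the residual above a threshold
#' are kept. Peak positions are refined by parabolic interpolation and the
#' full width at half maximum is measured by linear interpolation of the
#' half-height crossings.
#'
#' @param profile A [qprofile].
#' @param q_range Detection window (nm^-1). The default 0.2-1.05 covers
#'   diffraction orders 3-10 of a ~65 nm period while excluding the
#'   beamstop-affected first two orders.
#' @param smooth Width (points) of the moving-average smoother; 1 disables.
#' @param min_height_frac Minimum peak height as a fraction of the tallest
#'   detected structure.
#' @return A data frame with columns `q`, `height`, `fwhm` (one row per
#'   peak, ordered by q).
#' @export
detect_bragg_peaks <- function(profile, q_range = c(0.2, 1.05), smooth = 5,
                               min_height_frac = 0.005) {
  stopifnot(inherits(profile, "qprofile"))
  sel <- profile$q >= q_range[1] & profile$q <= q_range[2]
  q <- profile$q[sel]
  if (length(q) < 11) stop("too few points in the detection window")
  z <- profile$intensity[sel] * q^2
  if (smooth > 1) {
    zs <- as.numeric(stats::filter(z, rep(1 / smooth, smooth), sides = 2))
    zs[is.na(zs)] <- z[is.na(zs)]
  } else {
    zs <- z
  }
  k <- min(length(zs) - (1 - length(zs) %% 2), 51L)
  if (k %% 2 == 0) k <- k - 1
  base <- stats::runmed(zs, k)
  h <- zs - base

  # threshold: fraction of the tallest structure, or above the
  # point-to-point noise floor, whichever is larger
  noise <- stats::mad(diff(h)) / sqrt(2)
  thr <- max(min_height_frac * max(h), 8 * noise, 0)

  n <- length(h)
  cand <- which(h[2:(n - 1)] >= h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n] &
                  h[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0) {
    return(data.frame(q = numeric(0), height = numeric(0), fwhm = numeric(0)))
  }
  # merge plateau/noise-split maxima closer than 4 grid points
  keep <- logical(length(cand))
  ord <- order(h[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) > 4L)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- sort(cand[keep])

  # positions are refined by a parabola through the baseline-subtracted
  # intensity itself (not the q^2-weighted signal, whose envelope would
  # bias the apex)
  u <- profile$intensity[sel] - base / q^2
  refine <- function(i) {
    if (i <= 1L || i >= n) return(q[i])
    denom <- u[i - 1] - 2 * u[i] + u[i + 1]
    if (denom >= 0) return(q[i])
    dq <- (q[i + 1] - q[i - 1]) / 2
    q[i] + 0.5 * dq * (u[i - 1] - u[i + 1]) / denom
  }
  # widths are measured on the smoothed signal (stable under counting
  # noise); the smoother's boxcar broadening is removed in quadrature
  # below (boxcar variance W^2/12 -> Gaussian-equivalent FWHM 0.68 W)
  half_width <- function(i) {
    half <- h[i] / 2
    l <- i
    while (l > 1 && h[l] > half) l <- l - 1
    r <- i
    while (r < n && h[r] > half) r <- r + 1
    if (h[l] > half || h[r] > half) return(NA_real_)
    ql <- q[l] + (q[l + 1] - q[l]) * (half - h[l]) / (h[l + 1] - h[l])
    qr <- q[r - 1] + (q[r] - q[r - 1]) * (half - h[r - 1]) / (h[r] - h[r - 1])
    qr - ql
  }
  out <- data.frame(q = vapply(cand, refine, 0),
                    height = h[cand],
                    fwhm = vapply(cand, half_width, 0))
  dq <- stats::median(diff(q))
  if (smooth > 1) {
    broad <- 0.68 * smooth * dq
    out$fwhm <- sqrt(pmax(out$fwhm^2 - broad^2, (2 * dq)^2))
  }
  out$fwhm[!is.finite(out$fwhm)] <- 2 * dq
  # reject sub-resolution spikes and apexes of peaks cut by the window edge
  out <- out[out$fwhm >= 2 * dq &
               out$q > q[1] + 3 * dq & out$q < q[n] - 3 * dq, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  # suppress finite-grating sidelobes: secondary maxima of the N-period
  # interference function sit within ~1.5 peak widths of a stronger peak,
  # whereas adjacent diffraction orders are many widths apart
  ord <- order(out$height, decreasing = TRUE)
  acc <- integer(0)
  for (i in ord) {
    near <- abs(out$q[acc] - out$q[i]) <= 2.5 * out$fwhm[acc]
    if (!any(near)) acc <- c(acc, i)
  }
  out <- out[sort(acc), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$q), , drop = FALSE]
}

# Assign integer diffraction orders n to detected peak positions and
# estimate the period D = 2*pi/slope from a least-squares line through the
# origin. The Bragg lattice is first located from the strongest peaks:
# candidate fundamental spacings (the minimal inter-peak spacing and its
# half, in case even orders are suppressed) are combined with anchor
# orders {3, 5} for the most intense peak, and the assignment with the
# smallest regression residual wins. All detected peaks are then filtered
# for consistency with that lattice (which discards noise blips and
# window-edge artefacts), duplicate orders keep the stronger peak, and the
# slope is refit on the retained set.
.assign_orders <- function(peaks, D_init = NULL, d_range = c(50, 80)) {
  qp <- peaks$q
  if (length(qp) < 2) stop("insufficient orders: need at least 2 peaks")
  slope <- if (!is.null(D_init)) {
    2 * pi / D_init
  } else {
    .find_lattice(peaks, d_range = d_range)
  }
  keep <- seq_along(qp)
  nn <- round(qp / slope)
  for (it in 1:2) {
    nn <- round(qp / slope)
    ok <- nn >= 1 & abs(qp - nn * slope) <= 0.05 * slope
    keep <- which(ok)
    # duplicate order assignments: retain the stronger peak
    if (anyDuplicated(nn[keep])) {
      keep <- keep[order(peaks$height[keep], decreasing = TRUE)]
      keep <- sort(keep[!duplicated(nn[keep])])
    }
    if (length(keep) < 2) {
      stop("detected peaks inconsistent with a Bragg lattice")
    }
    slope <- sum(qp[keep] * nn[keep]) / sum(nn[keep]^2)
  }
  list(n = as.integer(nn[keep]), keep = keep, D_est = 2 * pi / slope,
       resid = sqrt(mean((qp[keep] - nn[keep] * slope)^2)) / slope)
}

# Locate the fundamental Bragg spacing s = 2*pi/D from the strongest
# detected peaks. Candidate spacings are pairwise position differences
# divided by small integers, restricted to the plausible period range;
# each candidate is scored by how many strong peaks fall on its lattice
# q = n * s (within 4% of s). Most inliers wins; ties prefer the largest
# spacing (the fundamental rather than a sub-harmonic).
.find_lattice <- function(peaks, d_range = c(50, 80)) {
  top <- sort(order(peaks$height, decreasing = TRUE)[seq_len(min(6L, nrow(peaks)))])
  qs <- peaks$q[top]
  smin <- 2 * pi / d_range[2]
  smax <- 2 * pi / d_range[1]
  cands <- numeric(0)
  if (length(qs) >= 2) {
    dd <- as.numeric(dist(qs))
    for (k in 1:8) {
      s <- dd / k
      cands <- c(cands, s[s >= smin & s <= smax])
    }
  }
  # absolute positions divided by small orders, in case diffs are sparse
  for (n in 3:12) {
    s <- qs / n
    cands <- c(cands, s[s >= smin & s <= smax])
  }
  if (!length(cands)) stop("could not assign diffraction orders")
  best <- NULL
  for (s in cands) {
    nn <- round(qs / s)
    inl <- nn >= 1 & abs(qs - nn * s) <= 0.04 * s
    n_in <- sum(inl)
    if (n_in < 2) next
    sl <- sum(qs[inl] * nn[inl]) / sum(nn[inl]^2)
    resid <- sqrt(mean((qs[inl] - sl * nn[inl])^2)) / sl
    if (is.null(best) || n_in > best$n_in ||
        (n_in == best$n_in && sl > best$slope * (1 + 1e-6)) ||
        (n_in == best$n_in && abs(sl - best$slope) <= best$slope * 1e-6 &&
         resid < best$resid)) {
      best <- list(slope = sl, n_in = n_in, resid = resid)
    }
  }
  if (is.null(best)) stop("could not assign diffraction orders")
  best$slope
}

# trapezoidal integral
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}
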