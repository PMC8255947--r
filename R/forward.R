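## Analytic time-domain diffusion forward model: infinite-space Green's
## function, slab geometry by the method of images (extrapolated boundaries),
## IRF convolution, area normalization and temporal-window binning.

#' Infinite-space time-domain Green's function
#'
#' Fluence at `r2` and time `t` due to an instantaneous isotropic point
#' source at `r1` at t = 0 in an infinite homogeneous medium:
#' \deqn{G(r_2, r_1, t) = v (4\pi v \kappa t)^{-3/2}
#'   e^{-|r_2 - r_1|^2 / (4 \kappa v t)} e^{-\mu_a v t}}
#' and 0 for t <= 0 (causality).
#'
#' @param r2 field point, length-3 numeric, mm
#' @param r1 source point, length-3 numeric, mm
#' @param t time(s), ps; vectorized
#' @param bg an [OpticalBackground-class]
#' @return fluence density, same length as `t`
#' @examples
#' bg <- opticalBackground(0.01, 1)
#' greenInfinite(c(10, 0, 0), c(0, 0, 0), c(-5, 0, 100, 500), bg)
#' @export
greenInfinite <- function(r2, r1, t, bg) {
  if (any(!is.finite(r2)) || any(!is.finite(r1)) || any(!is.finite(t)))
    stop("greenInfinite: non-finite input")
  rho2 <- sum((r2 - r1)^2)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- bg@v * (4 * pi * bg@v * bg@kappa * tp)^(-1.5) *
    exp(-rho2 / (4 * bg@kappa * bg@v * tp) - bg@mu_a * bg@v * tp)
  out
}

## z-coordinates and signs of the image-source series for a point source at
## depth z0 inside a slab [0, L] with extrapolated boundaries at -z_b and
## L + z_b. Returns the n_images most significant dipole pairs, ordered
## m = 0, -1, 1, -2, 2, ...
imageSourceTable <- function(z0, geom) {
  n <- as.integer(geom@n_images)
  ms <- integer(n)
  if (n > 1) {
    k <- seq_len(n - 1)
    ms[-1] <- ifelse(k %% 2 == 1, -(k + 1) %/% 2, (k + 1) %/% 2)
  }
  if (is.infinite(geom@thickness)) {
    ## single boundary: only the m = 0 dipole is nonzero
    return(data.frame(z = c(z0, -2 * geom@z_b - z0), sign = c(1, -1)))
  }
  le <- geom@thickness + 2 * geom@z_b
  zp <- 2 * ms * le + z0
  zm <- 2 * ms * le - 2 * geom@z_b - z0
  data.frame(z = c(rbind(zp, zm)), sign = rep(c(1, -1), times = n))
}

#' Slab-geometry time-domain Green's function
#'
#' Fluence in an infinite slab 0 <= z <= thickness with extrapolated
#' boundary conditions, evaluated as an alternating sum of
#' [greenInfinite()] terms over `n_images` image-source dipole pairs
#' reflected about the planes z = -z_b and z = thickness + z_b.
#'
#' @inheritParams greenInfinite
#' @param geom a [SlabGeometry-class]
#' @return fluence density, same length as `t`
#' @export
greenSlab <- function(r2, r1, t, bg, geom) {
  if (r1[3] < 0 || r2[3] < 0 || r1[3] > geom@thickness || r2[3] > geom@thickness)
    stop("greenSlab: point outside the slab")
  img <- imageSourceTable(r1[3], geom)
  out <- numeric(length(t))
  for (i in seq_len(nrow(img)))
    out <- out + img$sign[i] * greenInfinite(r2, c(r1[1], r1[2], img$z[i]), t, bg)
  out
}

#' Model TPSF for one source-detector pair
#'
#' Time-resolved reflectance model for a pair of surface optodes: the
#' source is an isotropic point one transport mean free path (1/mu_s')
#' below the source position, and the measurement is the fluence sampled
#' 1/mu_s' below the detector position.
#'
#' @param source,detector surface positions (length-3, z = 0), mm
#' @param bg an [OpticalBackground-class]
#' @param geom a [SlabGeometry-class]
#' @param axis a [TimeAxis-class]
#' @return a [TPSF-class] (not normalized, no IRF)
#' @examples
#' ax <- timeAxis(25, 164)
#' bg <- opticalBackground(0.01, 1)
#' curve <- forwardTPSF(c(0, -10, 0), c(12, -10, 0), bg, slabGeometry(40, bg), ax)
#' @export
forwardTPSF <- function(source, detector, bg, geom, axis) {
  stopifnot(abs(source[3]) < 1e-9, abs(detector[3]) < 1e-9)
  z0 <- 1 / bg@mu_s_prime
  if (sum((source[1:2] - detector[1:2])^2) == 0)
    message("forwardTPSF: zero source-detector separation (near-singular early bins)")
  vals <- greenSlab(c(detector[1], detector[2], z0), c(source[1], source[2], z0),
                    timePoints(axis), bg, geom)
  tpsf(vals, axis)
}

#' Convolve a TPSF with an instrument response function
#'
#' Discrete linear convolution (times dt, the rectangle-rule approximation
#' of the continuous convolution) truncated to the common time axis. With a
#' unit-area IRF the curve area is preserved up to the truncated tail.
#'
#' @param x a [TPSF-class]
#' @param irf a [TPSF-class] on the same axis
#' @return a [TPSF-class]
#' @export
convolveIRF <- function(x, irf) {
  ax <- x@axis
  if (ax@dt != irf@axis@dt || ax@n_t != irf@axis@n_t || ax@t0 != irf@axis@t0)
    stop("convolveIRF: mismatched time axes")
  tpsf(convolveDiscrete(x@values, irf@values, ax@dt), ax, x@sigma)
}

## rectangle-rule linear convolution of two equally-long sampled signals,
## truncated to the original length: out[m] = dt * sum_i x[i] y[m - i + 1]
convolveDiscrete <- function(x, y, dt) {
  n <- length(x)
  nf <- stats::nextn(2L * n, c(2, 3))
  xp <- c(x, numeric(nf - n)); yp <- c(y, numeric(nf - n))
  out <- Re(stats::fft(stats::fft(xp) * stats::fft(yp), inverse = TRUE)) / nf
  out[seq_len(n)] * dt
}

#' Area-normalize a TPSF over its ROI
#'
#' Scales the curve (and its sigma) so that the rectangle-rule integral
#' over the axis ROI equals 1, mirroring the area normalization applied to
#' measured time-domain data.
#'
#' @param x a [TPSF-class]
#' @return a [TPSF-class] with unit ROI area
#' @export
normalizeArea <- function(x) {
  roi <- x@axis@roi
  a <- sum(x@values[roi[1]:roi[2]]) * x@axis@dt
  if (!is.finite(a) || a <= 0) stop("normalizeArea: non-positive area over ROI")
  tpsf(x@values / a, x@axis, if (length(x@sigma)) x@sigma / a else numeric(0))
}

## window id (or NA) of every bin of the axis under a scheme
windowIndex <- function(axis, scheme) {
  tt <- timePoints(axis)
  id <- findInterval(tt, scheme@edges, left.open = FALSE, rightmost.closed = FALSE)
  id[id < 1 | id > nWindows(scheme)] <- NA
  id[tt >= scheme@edges[length(scheme@edges)]] <- NA
  as.integer(id)
}

#' Integrate a TPSF over temporal windows
#'
#' Window k holds the rectangle-rule integral of the curve over
#' [edges k, edges k+1); the per-window standard deviation is the propagated
#' standard deviation of that integral, sigma_k = dt * sqrt(sum sigma_i^2).
#' Windows must lie within the axis.
#'
#' @param x a [TPSF-class]
#' @param scheme a [WindowScheme-class]
#' @return list with `values` (length N_TW) and `sigma` (length N_TW, NA when
#'   the TPSF carries no sigma)
#' @export
binWindows <- function(x, scheme) {
  ax <- x@axis
  tt <- timePoints(ax)
  if (scheme@edges[1] < tt[1] - 1e-9 ||
      scheme@edges[length(scheme@edges)] > tt[ax@n_t] + ax@dt + 1e-9)
    stop("binWindows: window outside the time axis")
  id <- windowIndex(ax, scheme)
  k <- nWindows(scheme)
  vals <- vapply(seq_len(k), function(w) sum(x@values[which(id == w)]) * ax@dt, 0)
  sig <- if (length(x@sigma))
    vapply(seq_len(k), function(w) ax@dt * sqrt(sum(x@sigma[which(id == w)]^2)), 0)
  else rep(NA_real_, k)
  list(values = vals, sigma = sig)
}

#' Model TPSF matrix for a whole layout
#'
#' Computes the analytic model TPSF of every source-detector pair of a
#' layout, optionally convolved with an IRF and area-normalized.
#'
#' @param layout a [ProbeLayout-class]
#' @param bg an [OpticalBackground-class]
#' @param geom a [SlabGeometry-class]
#' @param axis a [TimeAxis-class]
#' @param irf optional [TPSF-class] instrument response
#' @param normalize area-normalize each curve over the ROI?
#' @return numeric matrix, pairs x n_t (row order = layout pair order)
#' @export
forwardTPSFSet <- function(layout, bg, geom, axis, irf = NULL, normalize = FALSE) {
  pr <- layout@pairs
  out <- matrix(0, nrow(pr), axis@n_t)
  z0 <- 1 / bg@mu_s_prime
  tt <- timePoints(axis)
  for (i in seq_len(nrow(pr))) {
    s <- layout@sources[pr[i, 1], ]; d <- layout@detectors[pr[i, 2], ]
    v <- greenSlab(c(d[1], d[2], z0), c(s[1], s[2], z0), tt, bg, geom)
    if (!is.null(irf)) v <- convolveDiscrete(v, irf@values, axis@dt)
    if (normalize) v <- v / (sum(v[axis@roi[1]:axis@roi[2]]) * axis@dt)
    out[i, ] <- v
  }
  out
}

#' Select a temporal ROI from a reference curve
#'
#' Default analysis region of interest: the contiguous span of bins where
#' the pooled reference TPSF is at least `frac` of its peak.
#'
#' @param values reference curve (vector) or matrix of curves (pairs x n_t)
#' @param axis a [TimeAxis-class]
#' @param frac threshold fraction of the peak (default 0.01)
#' @return a [TimeAxis-class] identical to `axis` but with the ROI set
#' @export
selectROI <- function(values, axis, frac = 0.01) {
  if (is.matrix(values)) values <- colSums(values)
  keep <- which(values >= frac * max(values))
  timeAxis(axis@dt, axis@n_t, axis@t0, roi = c(min(keep), max(keep)))
}
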