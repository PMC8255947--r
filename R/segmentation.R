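## Semi-automatic snake segmentation of a B-mode image: a closed periodic
## cubic-spline contour through N control points is driven by the sum of an
## internal bending energy and an image potential built from the squared
## distance transform of a smoothed-Laplacian percentile feature mask, plus
## a squared-distance repulsion from the user seed region. Minimization is
## repeated over a descending scale-space schedule, warm-starting each
## scale with the previous contour.

#' Ultrasound B-mode image container
#'
#' @slot pixels grayscale intensity matrix; rows run along x (lateral),
#'   columns along z (depth)
#' @slot pitch isotropic pixel pitch, mm/pixel
#' @slot origin (x, z) of pixel (1,1) center, mm (plane y = 0)
#' @exportClass USImage
setClass("USImage",
  representation(pixels = "matrix", pitch = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@pitch > 0)) msg <- c(msg, "pitch must be > 0")
    if (any(!is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a US image
#' @param pixels intensity matrix (x along rows, z along columns)
#' @param pitch pixel pitch, mm/pixel
#' @param origin (x, z) of pixel (1,1), mm; defaults to x centered, z from 0
#' @return a [USImage-class]
#' @export
usImage <- function(pixels, pitch = 0.25, origin = NULL) {
  if (is.null(origin)) origin <- c(-(nrow(pixels) - 1) / 2 * pitch, 0)
  new("USImage", pixels = pixels, pitch = pitch, origin = origin)
}

setMethod("show", "USImage", function(object) {
  cat(sprintf("USImage: %d x %d px at %g mm/px\n",
              nrow(object@pixels), ncol(object@pixels), object@pitch))
})

## mirror-pad a matrix by r rows/cols (reflection about the boundary pixel)
mirrorPad <- function(m, r, along) {
  n <- if (along == 1) nrow(m) else ncol(m)
  if (r >= n) stop("smoothing kernel larger than the image")
  idx <- c((r + 1):2, seq_len(n), (n - 1):(n - r))
  if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

## separable 1D convolution along rows (along = 1) or columns (along = 2)
convAxis <- function(m, kern, along) {
  r <- (length(kern) - 1L) %/% 2L
  if (r == 0) return(m * kern)
  p <- mirrorPad(m, r, along)
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kern)) {
    if (along == 1) out <- out + kern[k] * p[k:(k + nrow(m) - 1L), , drop = FALSE]
    else out <- out + kern[k] * p[, k:(k + ncol(m) - 1L), drop = FALSE]
  }
  out
}

gaussKernel1D <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smoothed Laplacian of an image
#'
#' Gaussian smoothing (unit-sum kernel, mirror borders) of the 5-point
#' discrete Laplacian of the image, in pixel units.
#'
#' @param image a [USImage-class] or a plain intensity matrix
#' @param sigma Gaussian scale, pixels (> 0)
#' @return matrix of the same size
#' @export
smoothedLaplacian <- function(image, sigma) {
  u <- if (is(image, "USImage")) image@pixels else image
  stopifnot(sigma > 0)
  p <- mirrorPad(mirrorPad(u, 1, 1), 1, 2)
  nr <- nrow(u); nc <- ncol(u)
  lap <- p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
         p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)] - 4 * u
  k <- gaussKernel1D(sigma)
  convAxis(convAxis(lap, k, 1), k, 2)
}

#' Low-percentile feature mask of a smoothed-Laplacian field
#'
#' Marks the pixels whose (signed, by default) smoothed-Laplacian value
#' falls below the `frac` percentile of the field: the strongly negative
#' band that traces hypoechoic lesion borders. Pixels strictly below the
#' threshold are taken first; tied pixels are added in raster order until
#' the mask holds at least `frac` of the pixels.
#'
#' @param lap 2D field (output of [smoothedLaplacian()])
#' @param frac percentile fraction (default 0.10)
#' @param use_abs threshold the magnitudes instead of the signed values?
#' @return binary matrix with attribute `threshold`
#' @export
featureMask <- function(lap, frac = 0.10, use_abs = FALSE) {
  v <- if (use_abs) abs(lap) else lap
  thr <- as.numeric(stats::quantile(v, frac, names = FALSE))
  mask <- v < thr
  need <- ceiling(frac * length(v)) - sum(mask)
  if (need > 0) {
    tied <- which(t(v) == thr)              # raster (row-major) order
    tied <- tied[seq_len(min(need, length(tied)))]
    tm <- t(mask); tm[tied] <- TRUE; mask <- t(tm)
  }
  out <- matrix(as.numeric(mask), nrow(lap), ncol(lap))
  attr(out, "threshold") <- thr
  out
}

#' Euclidean distance to the feature set
#'
#' Per-pixel Euclidean distance (pixels) to the nearest mask = 1 pixel
#' (0 on the features themselves). Exact Euclidean transform.
#'
#' @param mask binary matrix
#' @return distance matrix, pixels
#' @export
dtToFeatures <- function(mask) {
  if (sum(mask) == 0) stop("dtToFeatures: empty feature mask")
  as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(1 - (mask != 0)))))
}

#' Interior distance of a region
#'
#' Per-pixel Euclidean distance to the exterior of a binary region: 0
#' outside the region, growing towards its center. The maximum is the
#' region's inradius, used as the characteristic length of the scale
#' schedule.
#'
#' @param mask binary matrix
#' @return distance matrix, pixels
#' @export
interiorDistance <- function(mask) {
  as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask != 0))))
}

#' Image energy potential at one scale
#'
#' Squared distance to the smoothed-Laplacian feature set plus the squared
#' interior distance of the user seed region. The first term attracts the
#' contour to lesion-border features; the second repels it outward from
#' internal structures of the seeded area.
#'
#' @param image a [USImage-class] or matrix
#' @param sigma Laplacian smoothing scale, pixels
#' @param seed_mask binary matrix: the filled user seed polygon
#' @param use_abs passed to [featureMask()]
#' @return potential matrix (>= 0), pixel^2 units
#' @export
imageEnergy <- function(image, sigma, seed_mask, use_abs = FALSE) {
  if (sum(seed_mask) == 0) stop("imageEnergy: empty seed region")
  fm <- featureMask(smoothedLaplacian(image, sigma), use_abs = use_abs)
  dtToFeatures(fm)^2 + interiorDistance(seed_mask)^2
}

## dense samples of the closed periodic cubic spline through control
## points (m x 2), at `n` evenly spaced parameter values
splineSamples <- function(points, n) {
  np <- nrow(points)
  if (any(duplicated(points))) stop("degenerate (repeated) control points")
  tin <- 0:np
  tout <- seq(0, np, length.out = n + 1)[seq_len(n)]
  x <- stats::spline(tin, c(points[, 1], points[1, 1]), method = "periodic", xout = tout)$y
  y <- stats::spline(tin, c(points[, 2], points[1, 2]), method = "periodic", xout = tout)$y
  cbind(x, y)
}

#' Internal (bending) energy of a closed contour
#'
#' One half the arclength integral of a |C'|^2 + b |C''|^2 along the
#' unit-speed parametrization of the periodic cubic spline through the
#' control points, evaluated by dense sampling (at least 50 samples per
#' control point). For a circle of radius R with a = 0, b = 1 this is
#' pi / R.
#'
#' @param points control polygon, N x 2 (N >= 4)
#' @param a first-derivative (elasticity) weight
#' @param b second-derivative (bending) weight
#' @param n_samples dense sample count (default 50 per control point)
#' @return scalar energy
#' @export
internalEnergy <- function(points, a = 0, b = 1, n_samples = 50 * nrow(points)) {
  s <- splineSamples(points, n_samples)
  seg <- rbind(s[-1, ] - s[-nrow(s), ], s[1, ] - s[nrow(s), ])  # edge vectors
  dl <- sqrt(rowSums(seg^2))
  tang <- seg / dl
  dtang <- rbind(tang[-1, ] - tang[-nrow(tang), ], tang[1, ] - tang[nrow(tang), ])
  dl_mid <- (dl + c(dl[-1], dl[1])) / 2
  curv2 <- rowSums(dtang^2) / dl_mid^2
  0.5 * sum(a * dl + b * curv2 * dl_mid)
}

## bilinear interpolation of a matrix at continuous (row, col) positions,
## clamped to the image
bilinear <- function(m, pts) {
  i <- pmin(pmax(pts[, 1], 1), nrow(m)); j <- pmin(pmax(pts[, 2], 1), ncol(m))
  i0 <- pmin(floor(i), nrow(m) - 1L); j0 <- pmin(floor(j), ncol(m) - 1L)
  fi <- i - i0; fj <- j - j0
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) + m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j0 + 1)] * (1 - fi) * fj + m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

## total snake energy: internal + arclength integral of the potential
contourEnergy <- function(points, potential, a, b, n_samples = 50 * nrow(points)) {
  s <- splineSamples(points, n_samples)
  seg <- rbind(s[-1, ] - s[-nrow(s), ], s[1, ] - s[nrow(s), ])
  dl <- sqrt(rowSums(seg^2))
  internalEnergy(points, a, b, n_samples) + sum(bilinear(potential, s) * dl)
}

#' Minimize the snake energy at a fixed scale
#'
#' Gradient descent on the control-point coordinates of the total energy
#' (internal bending energy plus the arclength integral of the image
#' potential along the spline), with finite-difference gradients and a
#' backtracking step. Accepted steps never increase the energy; iteration
#' stops when the maximum control-point displacement falls below `tol` or
#' after `max_iter` iterations. Control points are clamped to the image
#' (with a warning) if a step pushes them outside.
#'
#' @param points initial control polygon, N x 2 (pixel coordinates)
#' @param potential image potential matrix
#' @param a,b internal energy weights
#' @param step initial trial displacement of the largest-gradient point, px
#' @param max_iter iteration cap
#' @param tol convergence displacement, px
#' @return list with `points` (final polygon) and `energies` (accepted
#'   energy sequence, non-increasing)
#' @export
minimizeAtScale <- function(points, potential, a = 0, b = 1, step = 0.8,
                            max_iter = 60, tol = 0.02) {
  np <- nrow(points)
  h <- 0.1
  energy <- function(p) contourEnergy(p, potential, a, b)
  e0 <- energy(points)
  energies <- e0
  for (iter in seq_len(max_iter)) {
    g <- matrix(0, np, 2)
    for (i in seq_len(np)) for (d in 1:2) {
      pp <- points; pp[i, d] <- pp[i, d] + h
      pm <- points; pm[i, d] <- pm[i, d] - h
      g[i, d] <- (energy(pp) - energy(pm)) / (2 * h)
    }
    gmax <- max(sqrt(rowSums(g^2)))
    if (gmax == 0) break
    s <- step
    accepted <- FALSE
    while (s > tol / 4) {
      cand <- points - g * (s / gmax)
      if (any(cand[, 1] < 1 | cand[, 1] > nrow(potential) |
              cand[, 2] < 1 | cand[, 2] > ncol(potential))) {
        warning("contour clamped to the image boundary")
        cand[, 1] <- pmin(pmax(cand[, 1], 1), nrow(potential))
        cand[, 2] <- pmin(pmax(cand[, 2], 1), ncol(potential))
      }
      e1 <- energy(cand)
      if (e1 < e0) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) break
    disp <- max(sqrt(rowSums((cand - points)^2)))
    points <- cand; e0 <- e1
    energies <- c(energies, e0)
    if (disp < tol) break
  }
  list(points = points, energies = energies)
}

## even-odd scanline fill of a closed polygon (continuous pixel coords)
## into an nr x nc binary matrix: pixel (i, j) is inside if the ray along
## increasing j crosses the polygon an odd number of times
fillPolygon <- function(poly, nr, nc) {
  m <- matrix(0, nr, nc)
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(nr)) {
    cross <- (x <= i & x2 > i) | (x2 <= i & x > i)
    if (!any(cross)) next
    jc <- y[cross] + (i - x[cross]) * (y2[cross] - y[cross]) / (x2[cross] - x[cross])
    jc <- sort(jc)
    for (k in seq(1, length(jc) - 1, by = 2)) {
      lo <- ceiling(jc[k]); hi <- floor(jc[k + 1])
      if (lo <= hi) m[i, max(1, lo):min(nc, hi)] <- 1
    }
  }
  m
}

## arclength-resample a control polygon to n points on its spline
resamplePolygon <- function(points, n = nrow(points)) {
  s <- splineSamples(points, 40 * nrow(points))
  seg <- rbind(s[-1, ] - s[-nrow(s), ], s[1, ] - s[nrow(s), ])
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
  total <- cum[length(cum)]
  targets <- seq(0, total, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(targets, cum, all.inside = TRUE)
  s[idx, , drop = FALSE]
}

#' Scale-space snake segmentation of a lesion
#'
#' Full semi-automatic segmentation: the user supplies at least 4 seed
#' points close to the lesion border on its internal side. The filled seed
#' polygon defines the repulsive term and the characteristic length r_hat
#' (its maximum interior distance); the snake is then minimized over
#' `n_scales` evenly spaced Laplacian scales descending from 0.7 r_hat to
#' 0.15 r_hat, warm-starting each scale with the previous contour. The
#' final contour is filled into a binary planar mask.
#'
#' @param image a [USImage-class]
#' @param seeds seed points, n x 2 matrix of (row, col) pixel coordinates
#' @param n_scales number of scales (default 15)
#' @param n_points control points of the snake (default: one per seed,
#'   resampled to at least 8)
#' @param a,b internal energy weights (defaults 0 and 1)
#' @param use_abs passed to [featureMask()]
#' @param max_iter descent iterations per scale
#' @return a [PlanarMask-class]; attributes `contour` (final dense contour,
#'   pixel coords) and `r_hat` are attached to its mask
#' @export
segmentLesion <- function(image, seeds, n_scales = 15, n_points = NULL,
                          a = 0, b = 1, use_abs = FALSE, max_iter = 60) {
  stopifnot(is(image, "USImage"))
  seeds <- rbind(seeds)
  if (nrow(seeds) < 4) stop("segmentLesion: need at least 4 seed points")
  px <- image@pixels
  seed_mask <- fillPolygon(seeds, nrow(px), ncol(px))
  if (sum(seed_mask) == 0) stop("segmentLesion: degenerate seed polygon")
  r_hat <- max(interiorDistance(seed_mask))
  sigmas <- seq(0.7 * r_hat, 0.15 * r_hat, length.out = n_scales)
  if (is.null(n_points)) n_points <- max(8, nrow(seeds))
  points <- resamplePolygon(seeds, n_points)
  for (sg in sigmas) {
    pot <- imageEnergy(image, sg, seed_mask, use_abs = use_abs)
    points <- minimizeAtScale(points, pot, a = a, b = b, max_iter = max_iter)$points
    points <- resamplePolygon(points, n_points)
  }
  contour <- splineSamples(points, 40 * n_points)
  mask <- fillPolygon(contour, nrow(px), ncol(px))
  mask <- as.matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))))
  pm <- planarMask(mask, image@pitch, image@origin)
  attr(pm, "contour") <- contour
  attr(pm, "r_hat") <- r_hat
  attr(pm, "sigmas") <- sigmas
  pm
}
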