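## Windowed Born sensitivity (Jacobian) assembly. The two temporal
## convolutions of the Born kernel (detector Green's function with the
## source fluence, then with the IRF) and the window integrals are all
## evaluated in the Fourier domain: for each source-detector pair the
## windowed kernel of every voxel is Re((F_det * F_src) %*% W) where W folds
## the IRF spectrum, the window indicators and all rectangle-rule dt factors
## into one nf x N_TW complex matrix. Zero-padding to >= 2 n_t avoids
## wrap-around.

## Time-domain slab fluence field (and its spatial gradient) from one
## optode at depth z0 below pos_xy, at `points` (np x 3), FFT'd along a
## zero-padded time axis. Returns nf x np complex matrices.
slabFieldsFFT <- function(points, pos_xy, z0, tt, bg, geom, nf, gradient = TRUE) {
  np <- nrow(points); n_t <- length(tt)
  pos <- tt > 0
  tp <- tt[pos]
  inv4 <- 1 / (4 * bg@kappa * bg@v * tp)
  inv2 <- 1 / (2 * bg@kappa * bg@v * tp)
  scale_t <- bg@v * (4 * pi * bg@v * bg@kappa * tp)^(-1.5) * exp(-bg@mu_a * bg@v * tp)
  dx <- points[, 1] - pos_xy[1]
  dy <- points[, 2] - pos_xy[2]
  img <- imageSourceTable(z0, geom)
  phi <- matrix(0, length(tp), np)
  if (gradient) { gx <- phi; gy <- phi; gz <- phi }
  for (i in seq_len(nrow(img))) {
    dz <- points[, 3] - img$z[i]
    rho2 <- dx^2 + dy^2 + dz^2
    e <- exp(outer(-inv4, rho2)) * scale_t * img$sign[i]
    phi <- phi + e
    if (gradient) {
      gx <- gx - e * outer(inv2, dx)
      gy <- gy - e * outer(inv2, dy)
      gz <- gz - e * outer(inv2, dz)
    }
  }
  pad <- function(m) {
    out <- matrix(0, nf, np)
    out[which(pos), ] <- m
    stats::mvfft(out)
  }
  if (gradient) list(phi = pad(phi), gx = pad(gx), gy = pad(gy), gz = pad(gz))
  else list(phi = pad(phi))
}

## Frequency-domain window operator: nf x N_TW complex matrix W such that
## for spectra X (nf x np) of the raw product G*Phi, Re(t(X) %*% W) gives
## the windowed, IRF-convolved kernel integrals (all dt factors included).
windowMatrixFFT <- function(axis, scheme, irf, nf) {
  k <- nWindows(scheme)
  id <- windowIndex(axis, scheme)
  w <- matrix(0, nf, k)
  for (j in seq_len(k)) w[which(id == j), j] <- 1
  wf <- Conj(stats::mvfft(w)) / nf
  fi <- if (is.null(irf)) 1 else stats::fft(c(irf@values, numeric(nf - axis@n_t))) * axis@dt
  (wf * fi) * axis@dt^2
}

## next fast FFT length >= 2 * n_t (factors 2 and 3)
fftLength <- function(n_t) stats::nextn(2L * as.integer(n_t), c(2, 3))

#' Windowed Born absorption sensitivity of voxels for one pair
#'
#' Born-approximation sensitivity of the windowed signal of one
#' source-detector pair to an absorption perturbation in each voxel:
#' minus the voxel volume times the temporal convolution of the detector
#' Green's function (source placed at the detector, by reciprocity) with
#' the source fluence, convolved with the IRF and integrated over the
#' temporal windows.
#'
#' @param source,detector surface optode positions (length-3, z = 0), mm
#' @param points voxel centers, n x 3 matrix, mm
#' @param volume voxel volume(s), mm^3 (scalar or length n)
#' @param bg an [OpticalBackground-class]
#' @param geom a [SlabGeometry-class]
#' @param axis a [TimeAxis-class]
#' @param scheme a [WindowScheme-class]
#' @param irf optional [TPSF-class] instrument response
#' @return n x N_TW matrix of windowed sensitivities (raw signal scale)
#' @export
sensitivityAbsorption <- function(source, detector, points, volume, bg, geom,
                                  axis, scheme, irf = NULL) {
  points <- rbind(points)
  tt <- timePoints(axis); nf <- fftLength(axis@n_t); z0 <- 1 / bg@mu_s_prime
  fs <- slabFieldsFFT(points, source[1:2], z0, tt, bg, geom, nf, gradient = FALSE)
  fd <- slabFieldsFFT(points, detector[1:2], z0, tt, bg, geom, nf, gradient = FALSE)
  w <- windowMatrixFFT(axis, scheme, irf, nf)
  -volume * Re(t(t(w) %*% (fs$phi * fd$phi)))
}

#' Windowed Born diffusion sensitivity of voxels for one pair
#'
#' As [sensitivityAbsorption()] but for a diffusion-coefficient
#' perturbation: the kernel is the dot product of the spatial gradients of
#' the detector Green's function and the source fluence, both taken at the
#' voxel (analytic gradients of the image-source series).
#'
#' @inheritParams sensitivityAbsorption
#' @return n x N_TW matrix of windowed sensitivities
#' @export
sensitivityDiffusion <- function(source, detector, points, volume, bg, geom,
                                 axis, scheme, irf = NULL) {
  points <- rbind(points)
  tt <- timePoints(axis); nf <- fftLength(axis@n_t); z0 <- 1 / bg@mu_s_prime
  fs <- slabFieldsFFT(points, source[1:2], z0, tt, bg, geom, nf)
  fd <- slabFieldsFFT(points, detector[1:2], z0, tt, bg, geom, nf)
  w <- windowMatrixFFT(axis, scheme, irf, nf)
  x <- fs$gx * fd$gx + fs$gy * fd$gy + fs$gz * fd$gz
  -volume * Re(t(t(w) %*% x))
}

#' Assemble the windowed Born system matrix
#'
#' Builds the full Jacobian for all pairs of a layout over a voxel grid:
#' rows ordered source-major, then detector, then window; columns
#' [delta mu_a block | delta kappa block]. The Jacobian is built once at
#' the homogeneous reference coefficients. With `normalize = TRUE`
#' (default, mirroring the area normalization of measured data) each
#' pair's rows are transformed into the differential of the area-normalized
#' windowed signal.
#'
#' @param layout a [ProbeLayout-class]
#' @param grid a [VoxelGrid-class]
#' @param bg an [OpticalBackground-class] (the linearization point)
#' @param geom a [SlabGeometry-class]
#' @param axis a [TimeAxis-class] whose ROI the scheme spans
#' @param scheme a [WindowScheme-class]
#' @param irf optional [TPSF-class] instrument response
#' @param normalize transform rows to the normalized-signal differential?
#' @param quad_points voxel quadrature: 1 = center rule (fast, default; the
#'   kernels are several voxels wide so the aggregate error is small), 2 =
#'   2 x 2 x 2 Gauss points per voxel (8x the field evaluations; brings the
#'   single-voxel column error below 1 percent even in the steep
#'   rising-edge windows)
#' @param chunk_size voxels processed per block
#' @param max_gb refuse assembly if the dense matrix would exceed this, GiB
#' @return a [SystemMatrix-class]
#' @export
assembleSystem <- function(layout, grid, bg, geom, axis, scheme, irf = NULL,
                           normalize = TRUE, quad_points = 1,
                           chunk_size = 2048, max_gb = 6) {
  stopifnot(quad_points %in% c(1, 2))
  npair <- nrow(layout@pairs); k <- nWindows(scheme); n <- nVoxels(grid)
  bytes <- npair * k * 2 * n * 8
  if (bytes > max_gb * 1024^3)
    stop(sprintf("assembleSystem: matrix would need %.1f GiB (budget %g GiB)",
                 bytes / 1024^3, max_gb))
  tt <- timePoints(axis); nf <- fftLength(axis@n_t); z0 <- 1 / bg@mu_s_prime
  w <- windowMatrixFFT(axis, scheme, irf, nf)
  wt <- t(w)                             # K x nf
  centers <- voxelCenters(grid)
  vol <- voxelVolume(grid)

  ## unique optode positions at sampling depth
  allpos <- rbind(layout@sources, layout@detectors)
  upos <- unique(allpos)
  posid <- function(p) which(upos[, 1] == p[1] & upos[, 2] == p[2])[1]
  sid <- apply(layout@sources, 1, posid)
  did <- apply(layout@detectors, 1, posid)

  ## quadrature nodes within each voxel (offsets from the center, mm)
  g1 <- grid@voxel / 2 / sqrt(3)
  qoffs <- if (quad_points == 1) list(c(0, 0, 0))
           else unname(as.list(as.data.frame(t(as.matrix(
             expand.grid(c(-g1, g1), c(-g1, g1), c(-g1, g1)))))))
  qw <- vol / length(qoffs)

  J <- matrix(0, npair * k, 2 * n)
  rowspan <- function(p) ((p - 1) * k + 1):(p * k)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  for (ch in chunks) {
    nc_ <- length(ch)
    ## accumulate the frequency-domain kernel spectra over the quadrature
    ## nodes, per unique unordered position pair (reciprocity)
    acc <- new.env(parent = emptyenv())
    keys <- character(npair)
    for (p in seq_len(npair)) {
      a <- sid[layout@pairs[p, 1]]; b <- did[layout@pairs[p, 2]]
      keys[p] <- paste(sort(c(a, b)), collapse = "-")
    }
    for (off in qoffs) {
      pts <- centers[ch, , drop = FALSE]
      pts[, 1] <- pts[, 1] + off[1]; pts[, 2] <- pts[, 2] + off[2]
      pts[, 3] <- pts[, 3] + off[3]
      fields <- lapply(seq_len(nrow(upos)), function(i)
        slabFieldsFFT(pts, upos[i, 1:2], z0, tt, bg, geom, nf))
      for (key in unique(keys)) {
        ab <- as.integer(strsplit(key, "-")[[1]])
        fa <- fields[[ab[1]]]; fb <- fields[[ab[2]]]
        ## windowing is linear, so accumulate the windowed blocks per node
        jmu <- Re(wt %*% (fa$phi * fb$phi))
        jka <- Re(wt %*% (fa$gx * fb$gx + fa$gy * fb$gy + fa$gz * fb$gz))
        cur <- get0(key, envir = acc)
        if (is.null(cur)) assign(key, list(mu = jmu, ka = jka), envir = acc)
        else assign(key, list(mu = cur$mu + jmu, ka = cur$ka + jka), envir = acc)
      }
    }
    for (p in seq_len(npair)) {
      blk <- get(keys[p], envir = acc)
      J[rowspan(p), ch] <- -qw * blk$mu
      J[rowspan(p), n + ch] <- -qw * blk$ka
    }
  }

  ## windowed raw model per pair, for the normalization differential
  model <- matrix(0, npair, k)
  raw <- forwardTPSFSet(layout, bg, geom, axis, irf = irf, normalize = FALSE)
  for (p in seq_len(npair))
    model[p, ] <- binWindows(tpsf(raw[p, ], axis), scheme)$values
  area <- rowSums(model)
  mhat <- model / area
  if (normalize) {
    for (p in seq_len(npair)) {
      idx <- rowspan(p)
      colsum <- colSums(J[idx, , drop = FALSE])
      J[idx, ] <- (J[idx, ] - tcrossprod(mhat[p, ], colsum)) / area[p]
    }
  }
  meta <- data.frame(source = rep(layout@pairs[, 1], each = k),
                     detector = rep(layout@pairs[, 2], each = k),
                     window = rep(seq_len(k), npair))
  new("SystemMatrix", J = J, row_meta = meta, grid = grid,
      model = mhat, normalized = normalize)
}

#' @describeIn assembleSystem dense Jacobian matrix accessor
#' @param system a `SystemMatrix`
#' @export
systemJacobian <- function(system) system@J

#' @describeIn assembleSystem windowed area-normalized model TPSFs (pairs x N_TW)
#' @export
systemModel <- function(system) system@model
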