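## 2D -> 3D extrusion of the planar segmentation via the distance-transform
## height function, and the edge-weighting field / first-order regularizer
## built from the extruded characteristic volume.

#' Distance-transform height function of a planar mask
#'
#' Height (out-of-plane half-extent, mm) of the extruded volume above each
#' in-plane pixel: with D the interior distance field of the mask (mm) and
#' r = sqrt(A / pi) the radius of the disk with the mask's area A,
#' \deqn{y_{ext}^2 = 2 r D - D^2.}
#' It vanishes on and outside the mask boundary, never exceeds r (the
#' radius of the sphere whose middle section has the mask's area), and maps
#' a disk exactly onto the equal-area sphere.
#'
#' @param mask a [PlanarMask-class]
#' @return matrix of heights, mm
#' @export
heightFunction <- function(mask) {
  if (sum(mask@mask) == 0) stop("heightFunction: empty mask")
  ## half-pixel offset: the discrete transform gives the distance between
  ## pixel centers, so a boundary pixel (center half a pixel inside the
  ## continuum boundary) reads 1; subtracting 0.5 px makes D the distance
  ## from the pixel center to the region boundary
  d <- (interiorDistance(mask@mask) - 0.5) * mask@pitch
  d[d < 0] <- 0
  r <- sqrt(maskArea(mask) / pi)
  y2 <- 2 * r * d - d^2
  y2[y2 < 0] <- 0
  sqrt(y2)
}

#' Extrude a planar mask into a 3D characteristic volume
#'
#' Voxel (x, y, z) belongs to the volume iff
#' (y - center_y)^2 < y_ext(x, z)^2, with the height function sampled
#' bilinearly at the voxel's (x, z) position in the mask raster. The
#' result is mirror-symmetric about the plane y = center_y.
#'
#' @param mask a [PlanarMask-class] (registered to the grid's x/z axes)
#' @param grid a [VoxelGrid-class]
#' @param center_y plane of the mask in the grid, mm (default 0)
#' @return a [VolumeMask-class]
#' @export
extrudeMask <- function(mask, grid, center_y = 0) {
  if (sum(mask@mask) == 0)
    return(new("VolumeMask", mask = array(0, gridDims(grid)), grid = grid))
  h <- heightFunction(mask)
  d <- gridDims(grid)
  xs <- grid@origin[1] + (seq_len(d[1]) - 1) * grid@voxel
  ys <- grid@origin[2] + (seq_len(d[2]) - 1) * grid@voxel
  zs <- grid@origin[3] + (seq_len(d[3]) - 1) * grid@voxel
  ## mask pixel support in mm
  sup_x <- mask@origin[1] + c(0, nrow(h) - 1) * mask@pitch
  sup_z <- mask@origin[2] + c(0, ncol(h) - 1) * mask@pitch
  occ <- which(mask@mask > 0, arr.ind = TRUE)
  occ_x <- mask@origin[1] + (range(occ[, 1]) - 1) * mask@pitch
  occ_z <- mask@origin[2] + (range(occ[, 2]) - 1) * mask@pitch
  if (occ_x[1] < min(xs) - grid@voxel / 2 || occ_x[2] > max(xs) + grid@voxel / 2 ||
      occ_z[1] < min(zs) - grid@voxel / 2 || occ_z[2] > max(zs) + grid@voxel / 2)
    warning("extrudeMask: mask footprint exceeds the grid; truncating")
  ## bilinear sample of the height field at grid (x, z)
  pi_ <- (rep(xs, times = d[3]) - mask@origin[1]) / mask@pitch + 1
  pj_ <- (rep(zs, each = d[1]) - mask@origin[2]) / mask@pitch + 1
  inside <- pi_ >= 1 & pi_ <= nrow(h) & pj_ >= 1 & pj_ <= ncol(h)
  hxz <- numeric(length(pi_))
  if (any(inside))
    hxz[inside] <- bilinear(h, cbind(pi_[inside], pj_[inside]))
  hxz <- matrix(hxz, d[1], d[3])              # x by z
  arr <- array(0, d)
  for (iy in seq_along(ys)) {
    dy2 <- (ys[iy] - center_y)^2
    arr[, iy, ] <- as.numeric(dy2 < hxz^2)
  }
  new("VolumeMask", mask = arr, grid = grid)
}

## separable 3D Gaussian smoothing (mirror borders), sigma in voxels
smooth3D <- function(arr, sigma) {
  k <- gaussKernel1D(sigma)
  d <- dim(arr)
  for (iz in seq_len(d[3])) arr[, , iz] <- convAxis(convAxis(arr[, , iz], k, 1), k, 2)
  m <- matrix(arr, d[1] * d[2], d[3])
  m <- t(convAxis(t(m), k, 1))
  array(m, d)
}

## central-difference gradient magnitude of a 3D array, spacing h (mm);
## one-sided differences at the domain faces
gradMagnitude3D <- function(arr, h) {
  d <- dim(arr)
  shift <- function(a, by, axis) {
    idx <- lapply(d, seq_len)
    src <- pmin(pmax(idx[[axis]] + by, 1), d[axis])
    args <- idx; args[[axis]] <- src
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  den <- function(axis) {
    n <- d[axis]
    sp <- pmin(seq_len(n) + 1, n) - pmax(seq_len(n) - 1, 1)
    sp * h
  }
  gx <- (shift(arr, 1, 1) - shift(arr, -1, 1)) / array(rep(den(1), times = d[2] * d[3]), d)
  gy <- (shift(arr, 1, 2) - shift(arr, -1, 2)) / array(rep(rep(den(2), each = d[1]), times = d[3]), d)
  gz <- (shift(arr, 1, 3) - shift(arr, -1, 3)) / array(rep(den(3), each = d[1] * d[2]), d)
  sqrt(gx^2 + gy^2 + gz^2)
}

#' Edge-weighting field from a characteristic volume
#'
#' gamma = exp(-|grad chi| / beta) per voxel, with the gradient magnitude
#' of the (optionally pre-smoothed) characteristic function taken by
#' central differences. gamma is 1 where chi is flat and smallest across
#' the volume's boundary, so the smoothness penalty is relaxed there.
#'
#' @param chi a [VolumeMask-class]
#' @param beta edge threshold; `NULL` (default) uses the 90th percentile of
#'   the nonzero gradient magnitudes
#' @param smooth_sigma Gaussian pre-smoothing of chi, voxels (default 1;
#'   0 disables)
#' @return an [EdgeWeightField-class]
#' @export
gammaField <- function(chi, beta = NULL, smooth_sigma = 1) {
  stopifnot(is(chi, "VolumeMask"))
  arr <- chi@mask * 1
  if (smooth_sigma > 0) arr <- smooth3D(arr, smooth_sigma)
  g <- gradMagnitude3D(arr, chi@grid@voxel)
  if (is.null(beta)) {
    nz <- g[g > 0]
    beta <- if (length(nz)) as.numeric(stats::quantile(nz, 0.9, names = FALSE)) else 1
  }
  if (beta <= 0) stop("gammaField: beta must be > 0")
  new("EdgeWeightField", gamma = exp(-g / beta), beta = beta, grid = chi@grid)
}

#' First-order (edge-weighted) regularization operator
#'
#' Sparse operator L with three rows per voxel (one forward difference per
#' axis, Neumann at the far faces) weighted by the square root of the
#' face-averaged gamma times the voxel volume, so that
#' \deqn{f^T L^T L f = \sum_{faces} \bar\gamma \, |\nabla f|^2 \, V_{vox}.}
#' Constant fields are in its null space. With gamma = 1 everywhere this
#' is the plain first-order Tikhonov operator.
#'
#' @param gamma an [EdgeWeightField-class], or a plain 3D array of weights
#'   (then `grid` must be given)
#' @param grid a [VoxelGrid-class] (taken from `gamma` if missing)
#' @return a sparse `dgCMatrix` with 3N rows and N columns
#' @export
buildRegularizer <- function(gamma, grid = NULL) {
  if (is(gamma, "EdgeWeightField")) { grid <- gamma@grid; gamma <- gamma@gamma }
  stopifnot(!is.null(grid))
  d <- gridDims(grid); n <- prod(d); h <- grid@voxel
  vol <- voxelVolume(grid)
  stride <- c(1L, d[1], d[1] * d[2])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  idx <- array(seq_len(n), d)
  for (axis in 1:3) {
    keep <- slice.index(idx, axis) < d[axis]
    from <- idx[keep]
    to <- from + stride[axis]
    w <- sqrt((gamma[from] + gamma[to]) / 2 * vol) / h
    row <- (axis - 1L) * n + from
    ii <- c(ii, row, row)
    jj <- c(jj, from, to)
    xx <- c(xx, -w, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * n, n))
}
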