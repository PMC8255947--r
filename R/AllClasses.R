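#' @import methods
#' @importFrom stats fft mvfft median sd quantile rnorm rpois runif spline approx setNames
#' @importFrom Matrix sparseMatrix Diagonal crossprod t
NULL

## Speed of light in vacuum, mm/ps. All lengths are mm, times ps,
## coefficients mm^-1 throughout the package.
C0_MM_PS <- 0.299792458

#' Homogeneous optical background
#'
#' Optical coefficients of the homogeneous medium around which the
#' reconstruction is linearized: absorption \eqn{\mu_a} (mm\eqn{^{-1}}),
#' reduced scattering \eqn{\mu_s'} (mm\eqn{^{-1}}), the derived diffusion
#' coefficient \eqn{\kappa = 1/(3\mu_s')} (mm) and the speed of light in the
#' medium \eqn{v = c_0/n} (mm/ps).
#'
#' @slot mu_a absorption coefficient, mm^-1
#' @slot mu_s_prime reduced scattering coefficient, mm^-1
#' @slot kappa diffusion coefficient, mm (always 1/(3*mu_s_prime))
#' @slot n_refr refractive index of the medium
#' @slot v speed of light in the medium, mm/ps
#' @exportClass OpticalBackground
setClass("OpticalBackground",
  representation(mu_a = "numeric", mu_s_prime = "numeric", kappa = "numeric",
                 n_refr = "numeric", v = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.finite(object@mu_a) || object@mu_a < 0)
      msg <- c(msg, "mu_a must be finite and >= 0")
    if (!is.finite(object@mu_s_prime) || object@mu_s_prime <= 0)
      msg <- c(msg, "mu_s_prime must be finite and > 0")
    if (!isTRUE(all.equal(object@kappa, 1 / (3 * object@mu_s_prime))))
      msg <- c(msg, "kappa must equal 1/(3*mu_s_prime)")
    if (!is.finite(object@v) || object@v <= 0)
      msg <- c(msg, "v must be finite and > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an optical background
#'
#' @param mu_a absorption coefficient, mm^-1
#' @param mu_s_prime reduced scattering coefficient, mm^-1
#' @param n_refr refractive index (default 1.54, silicone)
#' @return An [OpticalBackground-class] object.
#' @examples
#' bg <- opticalBackground(0.01, 1)
#' diffusionCoeff(bg)
#' @export
opticalBackground <- function(mu_a = 0.01, mu_s_prime = 1, n_refr = 1.54) {
  stopifnot(is.finite(mu_a), is.finite(mu_s_prime), is.finite(n_refr), n_refr >= 1)
  new("OpticalBackground", mu_a = mu_a, mu_s_prime = mu_s_prime,
      kappa = 1 / (3 * mu_s_prime), n_refr = n_refr, v = C0_MM_PS / n_refr)
}

#' @describeIn opticalBackground absorption coefficient accessor
#' @param object an `OpticalBackground`
#' @export
muA <- function(object) object@mu_a

#' @describeIn opticalBackground diffusion coefficient accessor, mm
#' @export
diffusionCoeff <- function(object) object@kappa

#' @describeIn opticalBackground speed of light in the medium, mm/ps
#' @export
lightSpeed <- function(object) object@v

setMethod("show", "OpticalBackground", function(object) {
  cat(sprintf("OpticalBackground: mu_a = %g mm^-1, mu_s' = %g mm^-1, kappa = %.4g mm, n = %g, v = %.4g mm/ps\n",
              object@mu_a, object@mu_s_prime, object@kappa, object@n_refr, object@v))
})

#' Slab geometry with extrapolated boundaries
#'
#' An infinite slab 0 <= z <= thickness. Boundary conditions are modelled by
#' the extrapolated-boundary construction: fluence vanishes on the planes
#' z = -z_b and z = thickness + z_b, enforced by an alternating series of
#' image-source dipole pairs.
#'
#' @slot thickness slab thickness, mm (`Inf` gives a semi-infinite medium)
#' @slot z_b extrapolation length, mm
#' @slot n_images number of image dipole pairs retained in the series
#' @exportClass SlabGeometry
setClass("SlabGeometry",
  representation(thickness = "numeric", z_b = "numeric", n_images = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@thickness > 0)) msg <- c(msg, "thickness must be > 0")
    if (!is.finite(object@z_b) || object@z_b <= 0) msg <- c(msg, "z_b must be finite and > 0")
    if (object@n_images < 1) msg <- c(msg, "n_images must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Effective internal reflection coefficient
#'
#' Polynomial fit of the Fresnel-moment effective reflection coefficient
#' R_eff as a function of the relative refractive index (Groenhuis-style fit),
#' used to set the extrapolation length z_b = 2*kappa*(1+R_eff)/(1-R_eff).
#'
#' @param n_refr relative refractive index of the medium against air
#' @return R_eff in [0, 1)
#' @export
effectiveReflection <- function(n_refr) {
  -1.440 / n_refr^2 + 0.710 / n_refr + 0.668 + 0.0636 * n_refr
}

#' Construct a slab geometry
#'
#' @param thickness slab thickness, mm; `Inf` for a semi-infinite medium
#' @param bg [OpticalBackground-class] supplying kappa and n for z_b
#' @param n_images number of image dipole pairs (default 7)
#' @return A [SlabGeometry-class] object.
#' @examples
#' geom <- slabGeometry(40, opticalBackground())
#' @export
slabGeometry <- function(thickness = 40, bg = opticalBackground(), n_images = 7) {
  reff <- effectiveReflection(bg@n_refr)
  zb <- 2 * bg@kappa * (1 + reff) / (1 - reff)
  new("SlabGeometry", thickness = thickness, z_b = zb, n_images = as.numeric(n_images))
}

setMethod("show", "SlabGeometry", function(object) {
  cat(sprintf("SlabGeometry: thickness = %g mm, z_b = %.3f mm, %d image pairs\n",
              object@thickness, object@z_b, as.integer(object@n_images)))
})

#' Probe layout: surface source and detector positions
#'
#' Source and detector positions on the z = 0 surface, plus the ordered list
#' of source-detector pairs measured. The default layout has eight optode
#' positions in two rows of four (12 mm pitch within a row, rows 20 mm
#' apart, straddling the ultrasound imaging plane y = 0) used both as
#' sources and detectors, giving 64 ordered pairs.
#'
#' @slot sources numeric matrix, one row per source, columns x,y,z (mm)
#' @slot detectors numeric matrix, one row per detector
#' @slot pairs integer matrix, columns (source index, detector index)
#' @exportClass ProbeLayout
setClass("ProbeLayout",
  representation(sources = "matrix", detectors = "matrix", pairs = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@sources) != 3 || ncol(object@detectors) != 3)
      msg <- c(msg, "positions must be N x 3 matrices")
    if (any(abs(object@sources[, 3]) > 1e-9) || any(abs(object@detectors[, 3]) > 1e-9))
      msg <- c(msg, "all optode positions must lie on the z = 0 plane")
    if (ncol(object@pairs) != 2) msg <- c(msg, "pairs must have 2 columns")
    if (any(object@pairs[, 1] < 1) || any(object@pairs[, 1] > nrow(object@sources)) ||
        any(object@pairs[, 2] < 1) || any(object@pairs[, 2] > nrow(object@detectors)))
      msg <- c(msg, "pair indices out of range")
    if (is.null(msg)) TRUE else msg
  })

#' Default two-row probe layout
#'
#' Eight optode positions arranged in two lines of four: 12 mm pitch along
#' each line (x direction), lines at y = -10 and y = +10 mm so the
#' ultrasound plane y = 0 runs between them. Every position acts as source
#' and detector; by default all 64 ordered combinations are measured.
#'
#' @param drop_coincident drop the 8 zero-separation (same-position) pairs?
#' @return A [ProbeLayout-class] with 64 (or 56) pairs.
#' @examples
#' nrow(probePairs(defaultProbeLayout()))  # 64
#' @export
defaultProbeLayout <- function(drop_coincident = FALSE) {
  xs <- c(-18, -6, 6, 18)
  pos <- cbind(x = rep(xs, 2), y = rep(c(-10, 10), each = 4), z = 0)
  pr <- as.matrix(expand.grid(source = seq_len(8), detector = seq_len(8)))
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  if (drop_coincident) pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  new("ProbeLayout", sources = pos, detectors = pos, pairs = pr)
}

#' Source-detector pair table of a layout
#' @param layout a [ProbeLayout-class]
#' @return integer matrix with columns (source, detector)
#' @export
probePairs <- function(layout) layout@pairs

setMethod("show", "ProbeLayout", function(object) {
  cat(sprintf("ProbeLayout: %d sources, %d detectors, %d pairs\n",
              nrow(object@sources), nrow(object@detectors), nrow(object@pairs)))
})

#' Uniform time axis for time-resolved histograms
#'
#' Samples sit at t_i = t0 + (i-1)*dt for i = 1..n_t. `roi` is the inclusive
#' index range [k_lo, k_hi] of the analysis region of interest.
#'
#' @slot t0 start time, ps
#' @slot dt bin width, ps
#' @slot n_t number of samples
#' @slot roi integer length-2 vector, inclusive ROI index range
#' @exportClass TimeAxis
setClass("TimeAxis",
  representation(t0 = "numeric", dt = "numeric", n_t = "numeric", roi = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@dt > 0)) msg <- c(msg, "dt must be > 0")
    if (object@n_t < 2) msg <- c(msg, "n_t must be >= 2")
    if (length(object@roi) != 2 || object@roi[1] < 1 || object@roi[2] > object@n_t ||
        object@roi[1] > object@roi[2])
      msg <- c(msg, "roi must be an index interval within [1, n_t]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a time axis
#' @param dt bin width, ps
#' @param n_t number of samples
#' @param t0 start time, ps (default 0)
#' @param roi inclusive ROI index range (default the full axis)
#' @return A [TimeAxis-class]
#' @export
timeAxis <- function(dt = 25, n_t = 164, t0 = 0, roi = c(1, n_t)) {
  new("TimeAxis", t0 = t0, dt = dt, n_t = as.numeric(n_t), roi = as.numeric(roi))
}

#' Sample times of an axis
#' @param axis a [TimeAxis-class]
#' @return numeric vector of sample times, ps
#' @export
timePoints <- function(axis) axis@t0 + (seq_len(axis@n_t) - 1) * axis@dt

#' Temporal point spread function (photon time-of-flight histogram)
#'
#' One time-resolved curve for a single source-detector pair: photon weight
#' (counts, count density, or area-normalized density) per time bin, with an
#' optional per-bin noise standard deviation.
#'
#' @slot values numeric vector of length n_t
#' @slot axis a [TimeAxis-class]
#' @slot sigma per-bin standard deviation (same length, or length 0)
#' @exportClass TPSF
setClass("TPSF",
  representation(values = "numeric", axis = "TimeAxis", sigma = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) != object@axis@n_t)
      msg <- c(msg, "values length must equal axis n_t")
    if (length(object@sigma) && length(object@sigma) != object@axis@n_t)
      msg <- c(msg, "sigma must be empty or of length n_t")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a TPSF
#' @param values photon weight per time bin
#' @param axis a [TimeAxis-class]
#' @param sigma optional per-bin standard deviation
#' @return a [TPSF-class]
#' @export
tpsf <- function(values, axis, sigma = numeric(0)) {
  new("TPSF", values = as.numeric(values), axis = axis, sigma = as.numeric(sigma))
}

#' Values of a TPSF
#' @param x a [TPSF-class]
#' @export
tpsfValues <- function(x) x@values

setMethod("show", "TPSF", function(object) {
  cat(sprintf("TPSF: %d bins, dt = %g ps, peak = %.4g at t = %g ps\n",
              as.integer(object@axis@n_t), object@axis@dt, max(object@values),
              timePoints(object@axis)[which.max(object@values)]))
})

#' Temporal window scheme
#'
#' N_TW contiguous windows [edges[k], edges[k+1]) partitioning the analysis
#' ROI. Each time bin belongs to exactly one window so the partition
#' identity (sum of window integrals = ROI integral) holds exactly.
#'
#' @slot edges strictly increasing vector of N_TW + 1 times, ps
#' @exportClass WindowScheme
setClass("WindowScheme",
  representation(edges = "numeric"),
  validity = function(object) {
    if (length(object@edges) < 2) return("need at least 2 edges")
    if (any(diff(object@edges) <= 0)) return("edges must be strictly increasing")
    TRUE
  })

#' Equally spaced windows over the ROI of an axis
#' @param axis a [TimeAxis-class]; windows span its ROI
#' @param n_windows number of windows (default 20)
#' @return a [WindowScheme-class]
#' @export
windowScheme <- function(axis, n_windows = 20) {
  tt <- timePoints(axis)
  lo <- tt[axis@roi[1]]; hi <- tt[axis@roi[2]] + axis@dt
  new("WindowScheme", edges = seq(lo, hi, length.out = n_windows + 1))
}

#' Number of windows in a scheme
#' @param scheme a [WindowScheme-class]
#' @export
nWindows <- function(scheme) length(scheme@edges) - 1L

#' Voxel grid of the reconstruction domain
#'
#' Cuboid domain discretized with cubic voxels. The default reproduces the
#' reconstruction domain used throughout: 64 mm x 58 mm x 32 mm at 2 mm
#' voxels (32 x 29 x 16 = 14848 voxels), centered under the probe with the
#' ultrasound plane at y = 0 and the surface at z = 0.
#'
#' @slot origin coordinates of the first voxel center, mm
#' @slot voxel cubic voxel side, mm
#' @slot dims integer voxel counts (nx, ny, nz)
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(origin = "numeric", voxel = "numeric", dims = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@voxel > 0)) msg <- c(msg, "voxel side must be > 0")
    if (length(object@dims) != 3 || any(object@dims < 1))
      msg <- c(msg, "dims must be 3 positive counts")
    if (length(object@origin) != 3) msg <- c(msg, "origin must have 3 components")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a voxel grid
#'
#' @param extents physical extents (x, y, z), mm
#' @param voxel cubic voxel side, mm
#' @param center_xy center the x and y extents about 0? (z always starts at 0)
#' @return a [VoxelGrid-class]; voxel centers are at
#'   origin + (i-1)*voxel along each axis.
#' @examples
#' g <- voxelGrid()          # 32 x 29 x 16 voxels, 2 mm side
#' prod(gridDims(g))         # 14848
#' @export
voxelGrid <- function(extents = c(64, 58, 32), voxel = 2, center_xy = TRUE) {
  dims <- round(extents / voxel)
  origin <- c(if (center_xy) -extents[1] / 2 else 0,
              if (center_xy) -extents[2] / 2 else 0,
              0) + voxel / 2
  new("VoxelGrid", origin = origin, voxel = voxel, dims = as.numeric(dims))
}

#' @describeIn voxelGrid integer voxel counts (nx, ny, nz)
#' @param grid a [VoxelGrid-class]
#' @export
gridDims <- function(grid) as.integer(grid@dims)

#' @describeIn voxelGrid number of voxels N
#' @export
nVoxels <- function(grid) prod(as.integer(grid@dims))

#' @describeIn voxelGrid voxel volume, mm^3
#' @export
voxelVolume <- function(grid) grid@voxel^3

#' @describeIn voxelGrid voxel-center coordinates as an N x 3 matrix (x fastest)
#' @export
voxelCenters <- function(grid) {
  d <- gridDims(grid)
  xs <- grid@origin[1] + (seq_len(d[1]) - 1) * grid@voxel
  ys <- grid@origin[2] + (seq_len(d[2]) - 1) * grid@voxel
  zs <- grid@origin[3] + (seq_len(d[3]) - 1) * grid@voxel
  cbind(x = rep(xs, times = d[2] * d[3]),
        y = rep(rep(ys, each = d[1]), times = d[3]),
        z = rep(zs, each = d[1] * d[2]))
}

setMethod("show", "VoxelGrid", function(object) {
  d <- gridDims(object)
  cat(sprintf("VoxelGrid: %d x %d x %d voxels of %g mm (N = %d)\n",
              d[1], d[2], d[3], object@voxel, prod(d)))
})

#' Windowed Born system matrix
#'
#' Stacked windowed Born sensitivity blocks for absorption and diffusion
#' perturbations. Rows are ordered source-major, then detector, then window;
#' columns are [delta mu_a block | delta kappa block] over the voxel grid.
#'
#' @slot J dense numeric matrix (N_Q*M*N_TW rows, 2N columns)
#' @slot row_meta data.frame with columns source, detector, window
#' @slot grid the [VoxelGrid-class] of the columns
#' @slot model windowed area-normalized model TPSFs, pairs x N_TW
#' @slot normalized logical: are rows differentials of area-normalized data?
#' @exportClass SystemMatrix
setClass("SystemMatrix",
  representation(J = "matrix", row_meta = "data.frame", grid = "VoxelGrid",
                 model = "matrix", normalized = "logical"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@J) != 2 * nVoxels(object@grid))
      msg <- c(msg, "J must have 2N columns")
    if (nrow(object@J) != nrow(object@row_meta) * 1L &&
        nrow(object@row_meta) != nrow(object@J))
      msg <- c(msg, "row metadata must match row count")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SystemMatrix", function(object) {
  cat(sprintf("SystemMatrix: %d rows (%d pairs x %d windows), %d columns (2 x %d voxels)%s\n",
              nrow(object@J), nrow(object@model), ncol(object@model),
              ncol(object@J), nVoxels(object@grid),
              if (object@normalized) ", area-normalized" else ""))
})

#' Planar binary mask in the ultrasound plane
#'
#' Binary characteristic function chi_P of the segmented lesion on the
#' (x, z) pixel raster of the B-mode image. Row index runs along x, column
#' index along z (depth).
#'
#' @slot mask numeric/logical matrix (1 inside the lesion)
#' @slot pitch isotropic pixel pitch, mm/pixel
#' @slot origin (x, z) of pixel (1, 1) center, mm
#' @exportClass PlanarMask
setClass("PlanarMask",
  representation(mask = "matrix", pitch = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@pitch > 0)) msg <- c(msg, "pitch must be > 0")
    if (length(object@origin) != 2) msg <- c(msg, "origin must be (x, z)")
    if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must be binary")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a planar mask
#' @param mask binary matrix (x along rows, z along columns)
#' @param pitch pixel pitch, mm/pixel (isotropic)
#' @param origin (x, z) of pixel (1,1) center in mm; default centers x about
#'   0 and puts z = 0 at the first column
#' @return a [PlanarMask-class]
#' @export
planarMask <- function(mask, pitch, origin = NULL) {
  mask <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (is.null(origin)) origin <- c(-(nrow(mask) - 1) / 2 * pitch, 0)
  new("PlanarMask", mask = mask, pitch = pitch, origin = origin)
}

#' Area of a planar mask, mm^2
#' @param mask a [PlanarMask-class]
#' @export
maskArea <- function(mask) sum(mask@mask) * mask@pitch^2

setMethod("show", "PlanarMask", function(object) {
  cat(sprintf("PlanarMask: %d x %d px at %g mm/px, area = %.1f mm^2\n",
              nrow(object@mask), ncol(object@mask), object@pitch, maskArea(object)))
})

#' Binary characteristic volume on a voxel grid
#'
#' @slot mask 3D binary array on the grid
#' @slot grid the [VoxelGrid-class]
#' @exportClass VolumeMask
setClass("VolumeMask",
  representation(mask = "array", grid = "VoxelGrid"),
  validity = function(object) {
    if (!all(dim(object@mask) == gridDims(object@grid)))
      return("mask dimensions must match the grid")
    TRUE
  })

setMethod("show", "VolumeMask", function(object) {
  cat(sprintf("VolumeMask: %s voxels set of %d (volume = %.0f mm^3)\n",
              format(sum(object@mask)), nVoxels(object@grid),
              sum(object@mask) * voxelVolume(object@grid)))
})

#' Edge-weighting field gamma
#'
#' Per-voxel weight gamma = exp(-|grad chi| / beta) in [0, 1]: close to 1
#' away from the prior volume's edges, small across them, so the first-order
#' smoothness penalty is relaxed exactly where the ultrasound prior places
#' a boundary.
#'
#' @slot gamma 3D array of weights in [0, 1]
#' @slot beta edge threshold parameter used
#' @slot grid the [VoxelGrid-class]
#' @exportClass EdgeWeightField
setClass("EdgeWeightField",
  representation(gamma = "array", beta = "numeric", grid = "VoxelGrid"),
  validity = function(object) {
    msg <- NULL
    if (any(object@gamma < 0) || any(object@gamma > 1))
      msg <- c(msg, "gamma must lie in [0, 1]")
    if (!(object@beta > 0)) msg <- c(msg, "beta must be > 0")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "EdgeWeightField", function(object) {
  cat(sprintf("EdgeWeightField: beta = %.4g, min gamma = %.3f, %.1f%% of voxels < 0.99\n",
              object@beta, min(object@gamma), 100 * mean(object@gamma < 0.99)))
})

#' Reconstruction result
#'
#' Voxel fields of the reconstructed perturbations delta mu_a (mm^-1) and
#' delta kappa (mm), with solver diagnostics.
#'
#' @slot delta_mu_a 3D array, mm^-1
#' @slot delta_kappa 3D array, mm
#' @slot grid the [VoxelGrid-class]
#' @slot alpha regularization weight used
#' @slot iterations LSQR iterations performed
#' @slot residual final relative residual norm
#' @exportClass ReconstructionResult
setClass("ReconstructionResult",
  representation(delta_mu_a = "array", delta_kappa = "array", grid = "VoxelGrid",
                 alpha = "numeric", iterations = "numeric", residual = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@delta_mu_a) == gridDims(object@grid)))
      msg <- c(msg, "delta_mu_a dimensions must match the grid")
    if (!all(dim(object@delta_kappa) == gridDims(object@grid)))
      msg <- c(msg, "delta_kappa dimensions must match the grid")
    if (any(!is.finite(object@delta_mu_a)) || any(!is.finite(object@delta_kappa)))
      msg <- c(msg, "fields must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn reconstruct reconstructed absorption perturbation field (3D array, mm^-1)
#' @param result a `ReconstructionResult`
#' @export
deltaMuA <- function(result) result@delta_mu_a

#' @describeIn reconstruct reconstructed diffusion perturbation field (3D array, mm)
#' @export
deltaKappa <- function(result) result@delta_kappa

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf("ReconstructionResult: delta_mu_a in [%.3g, %.3g] mm^-1, alpha = %.3g, %d LSQR iterations\n",
              min(object@delta_mu_a), max(object@delta_mu_a), object@alpha,
              as.integer(object@iterations)))
})

#' Phantom specification for the synthetic generator
#'
#' Dual-modality phantom: homogeneous bulk slab plus one cylindrical
#' inclusion whose axis is perpendicular to the ultrasound plane (y axis).
#' Defaults reproduce the silicone phantom set: 40 mm bulk with
#' mu_s' = 1 mm^-1 and mu_a = 0.01 mm^-1; 11 mm diameter x 10 mm height
#' cylinder (about 950 mm^3) under a 5 mm cover, inclusion absorption from
#' 0.005 to 0.06 mm^-1.
#'
#' @slot bulk [OpticalBackground-class] of the bulk
#' @slot thickness slab thickness, mm
#' @slot incl_center inclusion center (x, y, z), mm
#' @slot incl_diameter cylinder diameter, mm
#' @slot incl_height cylinder height (along y), mm
#' @slot incl_mu_a inclusion absorption, mm^-1
#' @slot incl_mu_s_prime inclusion reduced scattering, mm^-1
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(bulk = "OpticalBackground", thickness = "numeric",
                 incl_center = "numeric", incl_diameter = "numeric",
                 incl_height = "numeric", incl_mu_a = "numeric",
                 incl_mu_s_prime = "numeric"),
  validity = function(object) {
    msg <- NULL
    zc <- object@incl_center[3]; r <- object@incl_diameter / 2
    if (zc - r < 0 || zc + r > object@thickness)
      msg <- c(msg, "inclusion must lie inside the slab")
    if (object@incl_mu_a < 0) msg <- c(msg, "inclusion mu_a must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a phantom specification
#'
#' @param mu_a_in inclusion absorption, mm^-1 (default 0.02, one of the
#'   nominal set 0.005, 0.01, 0.02, 0.04, 0.06)
#' @param bulk bulk optical background
#' @param thickness slab thickness, mm
#' @param cover_depth depth of the top of the inclusion below the surface, mm
#' @param diameter,height cylinder diameter and height, mm
#' @param mu_s_prime_in inclusion reduced scattering, mm^-1
#' @param center_xy lateral (x, y) position of the cylinder axis, mm
#' @return a [PhantomSpec-class]
#' @examples
#' spec <- phantomSpec(mu_a_in = 0.04)
#' @export
phantomSpec <- function(mu_a_in = 0.02, bulk = opticalBackground(0.01, 1),
                        thickness = 40, cover_depth = 5, diameter = 11,
                        height = 10, mu_s_prime_in = 1, center_xy = c(0, 0)) {
  center <- c(center_xy, cover_depth + diameter / 2)
  new("PhantomSpec", bulk = bulk, thickness = thickness, incl_center = center,
      incl_diameter = diameter, incl_height = height,
      incl_mu_a = mu_a_in, incl_mu_s_prime = mu_s_prime_in)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: bulk mu_a = %g, inclusion mu_a = %g mm^-1 (NC = %.2g), cylinder %g x %g mm at (%g, %g, %g) mm\n",
              object@bulk@mu_a, object@incl_mu_a, object@incl_mu_a / object@bulk@mu_a,
              object@incl_diameter, object@incl_height,
              object@incl_center[1], object@incl_center[2], object@incl_center[3]))
})
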