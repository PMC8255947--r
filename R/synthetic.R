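## Synthetic dual-modality phantom generator: time-resolved optical
## measurements (analytic homogeneous reference plus a first-order Born
## perturbation of the true inclusion evaluated on a refined sub-voxel
## grid, convolved with a Gaussian IRF and Poisson-sampled) and speckled
## B-mode-like images with an anechoic inclusion.

#' Set of time-resolved curves for all pairs of a layout
#'
#' @slot values pairs x n_t matrix of photon weights
#' @slot sigma pairs x n_t matrix of per-bin standard deviations (may be
#'   0 x 0 when noise-free)
#' @slot axis the common [TimeAxis-class]
#' @exportClass TPSFSet
setClass("TPSFSet",
  representation(values = "matrix", sigma = "matrix", axis = "TimeAxis"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@values) != object@axis@n_t)
      msg <- c(msg, "values must have n_t columns")
    if (length(object@sigma) && !all(dim(object@sigma) == dim(object@values)))
      msg <- c(msg, "sigma must match values")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a TPSF set
#' @param values pairs x n_t matrix
#' @param axis a [TimeAxis-class]
#' @param sigma optional matching matrix of standard deviations
#' @return a [TPSFSet-class]
#' @export
tpsfSet <- function(values, axis, sigma = matrix(0, 0, 0)) {
  new("TPSFSet", values = values, sigma = sigma, axis = axis)
}

#' Extract one pair's curve from a set
#' @param x a [TPSFSet-class]
#' @param i pair index
#' @return a [TPSF-class]
#' @export
tpsfAt <- function(x, i) {
  tpsf(x@values[i, ], x@axis,
       if (length(x@sigma)) x@sigma[i, ] else numeric(0))
}

setMethod("show", "TPSFSet", function(object) {
  cat(sprintf("TPSFSet: %d pairs x %d bins (dt = %g ps)%s\n",
              nrow(object@values), as.integer(object@axis@n_t), object@axis@dt,
              if (length(object@sigma)) ", with noise sigma" else ""))
})

#' Gaussian instrument response function
#'
#' Unit-area Gaussian on the axis, centered at `t_center` (default twice
#' the FWHM so the curve is essentially fully supported on t > 0).
#'
#' @param fwhm full width at half maximum, ps
#' @param axis a [TimeAxis-class]
#' @param t_center peak time, ps
#' @return a [TPSF-class] with unit area
#' @export
makeIRF <- function(fwhm, axis, t_center = 2 * fwhm) {
  stopifnot(fwhm > 0)
  if (fwhm < 2 * axis@dt)
    warning("makeIRF: FWHM below 2*dt; the sampled IRF is aliased")
  sdv <- fwhm / (2 * sqrt(2 * log(2)))
  tt <- timePoints(axis)
  v <- exp(-(tt - t_center)^2 / (2 * sdv^2))
  tpsf(v / (sum(v) * axis@dt), axis)
}

## centers (m x 3) and volume of the refined voxelization of the
## cylindrical inclusion (axis along y)
inclusionSubvoxels <- function(spec, pitch) {
  r <- spec@incl_diameter / 2; hh <- spec@incl_height / 2
  cc <- spec@incl_center
  xs <- seq(cc[1] - r + pitch / 2, cc[1] + r, by = pitch)
  ys <- seq(cc[2] - hh + pitch / 2, cc[2] + hh, by = pitch)
  zs <- seq(cc[3] - r + pitch / 2, cc[3] + r, by = pitch)
  g <- expand.grid(x = xs, y = ys, z = zs)
  keep <- (g$x - cc[1])^2 + (g$z - cc[3])^2 < r^2 & abs(g$y - cc[2]) < hh
  list(centers = as.matrix(g[keep, , drop = FALSE]), volume = pitch^3)
}

## noiseless Born perturbation curves delta y(t) for every pair of the
## layout, from the true inclusion voxelized at `pitch`
bornPerturbation <- function(spec, layout, axis, irf, pitch) {
  bg <- spec@bulk
  geom <- slabGeometry(spec@thickness, bg)
  sub <- inclusionSubvoxels(spec, pitch)
  d_mu <- spec@incl_mu_a - bg@mu_a
  d_ka <- 1 / (3 * spec@incl_mu_s_prime) - bg@kappa
  n_t <- axis@n_t; nf <- fftLength(n_t)
  tt <- timePoints(axis); z0 <- 1 / bg@mu_s_prime
  fi <- if (is.null(irf)) 1 else stats::fft(c(irf@values, numeric(nf - n_t))) * axis@dt
  need_grad <- abs(d_ka) > 0
  allpos <- rbind(layout@sources, layout@detectors)
  upos <- unique(allpos)
  posid <- function(p) which(upos[, 1] == p[1] & upos[, 2] == p[2])[1]
  sid <- apply(layout@sources, 1, posid)
  did <- apply(layout@detectors, 1, posid)
  fields <- lapply(seq_len(nrow(upos)), function(i)
    slabFieldsFFT(sub$centers, upos[i, 1:2], z0, tt, bg, geom, nf,
                  gradient = need_grad))
  npair <- nrow(layout@pairs)
  out <- matrix(0, npair, n_t)
  cache <- new.env(parent = emptyenv())
  for (p in seq_len(npair)) {
    a <- sid[layout@pairs[p, 1]]; b <- did[layout@pairs[p, 2]]
    key <- paste(sort(c(a, b)), collapse = "-")
    val <- get0(key, envir = cache)
    if (is.null(val)) {
      fa <- fields[[a]]; fb <- fields[[b]]
      spec_mu <- rowSums(fa$phi * fb$phi)
      acc <- -sub$volume * d_mu * spec_mu
      if (need_grad) {
        spec_ka <- rowSums(fa$gx * fb$gx + fa$gy * fb$gy + fa$gz * fb$gz)
        acc <- acc - sub$volume * d_ka * spec_ka
      }
      ## one dt for the G (*) Phi convolution; fi already carries the dt of
      ## the IRF convolution
      val <- Re(stats::fft(acc * fi, inverse = TRUE))[seq_len(n_t)] / nf * axis@dt
      assign(key, val, envir = cache)
    }
    out[p, ] <- val
  }
  out
}

#' Simulate dual-phantom time-resolved measurements
#'
#' Generates the reference measurement on the sole bulk (analytic slab
#' model convolved with a Gaussian IRF) and the inclusion measurement
#' (reference plus the first-order Born perturbation of the true cylinder,
#' integrated over a sub-voxel grid `fine_factor` times finer than the
#' reconstruction voxels, mitigating the inverse crime of sharing the
#' reconstruction discretization). Both are Poisson-sampled at
#' `counts` photons per pair and returned as count densities with
#' propagated per-bin standard deviations.
#'
#' @param spec a [PhantomSpec-class]
#' @param layout a [ProbeLayout-class]
#' @param axis a [TimeAxis-class]
#' @param counts total detected photons per pair (default 1e6)
#' @param irf_fwhm IRF width, ps (default 250); NULL disables the IRF
#' @param recon_voxel reconstruction voxel side the refinement is relative
#'   to, mm (default 2)
#' @param fine_factor sub-voxel refinement factor (default 4)
#' @param noiseless skip Poisson sampling (sigma still reflects `counts`)
#' @return list with `y_ref` and `y` ([TPSFSet-class]), `irf` ([TPSF-class])
#' @export
simulateMeasurements <- function(spec, layout = defaultProbeLayout(),
                                 axis = timeAxis(25, 164), counts = 1e6,
                                 irf_fwhm = 250, recon_voxel = 2,
                                 fine_factor = 4, noiseless = FALSE) {
  bg <- spec@bulk
  geom <- slabGeometry(spec@thickness, bg)
  irf <- if (is.null(irf_fwhm)) NULL else makeIRF(irf_fwhm, axis)
  y_ref <- forwardTPSFSet(layout, bg, geom, axis, irf = irf)
  dy <- bornPerturbation(spec, layout, axis, irf, recon_voxel / fine_factor)
  y <- y_ref + dy
  if (min(y) < 0) y[y < 0] <- 0
  sample_set <- function(raw) {
    lam <- raw / rowSums(raw * axis@dt) * counts * axis@dt   # expected counts/bin
    lam[lam < 0] <- 0
    if (noiseless) {
      vals <- lam / (counts * axis@dt)
      sig <- sqrt(pmax(lam, 1)) / (counts * axis@dt)
    } else {
      k <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
      vals <- k / (counts * axis@dt)
      sig <- sqrt(pmax(k, 1)) / (counts * axis@dt)
    }
    tpsfSet(vals, axis, sig)
  }
  list(y_ref = sample_set(y_ref), y = sample_set(y), irf = irf)
}

#' Synthetic B-mode-like speckle image of the phantom
#'
#' Statistical look-alike of a B-mode scan of the phantom's ultrasound
#' plane (y = 0), emulating a zoomed scan of the anechoic silicone
#' inclusion inside the echogenic bulk: multiplicative squared-Rayleigh
#' speckle texture (`looks` incoherently averaged looks give the display's
#' speckle contrast, 1/sqrt(looks)) over a background of mean intensity 1;
#' the inclusion cross-section at reduced mean `contrast`; a bright
#' specular interface echo along the inclusion boundary (the acoustic
#' impedance mismatch of the two silicones); and an optional posterior
#' shadow band. The exact inclusion cross-section is returned as the
#' ground-truth mask.
#'
#' @param spec a [PhantomSpec-class]
#' @param pitch pixel pitch, mm/pixel (default 0.25)
#' @param extent_x,extent_z imaged extents, mm (default: a 32 x 20 mm
#'   window centered laterally on the inclusion, as a sonographer would
#'   zoom it)
#' @param contrast inclusion/background mean-intensity ratio (default 0.25)
#' @param grain speckle grain (Gaussian correlation length), pixels
#' @param looks number of incoherent looks (4 gives the display's typical
#'   speckle contrast of 0.5)
#' @param rim_amp peak mean intensity of the specular boundary echo, above
#'   background (default 2; 0 disables)
#' @param rim_width Gaussian half-width of the boundary echo, mm
#' @param shadow multiplicative intensity of a posterior shadow band below
#'   the inclusion (1 = no shadow, the default)
#' @return list with `image` ([USImage-class]) and `truth` ([PlanarMask-class])
#' @export
synthUSImage <- function(spec, pitch = 0.25, extent_x = 32, extent_z = 20,
                         contrast = 0.25, grain = 1, looks = 4,
                         rim_amp = 2, rim_width = 0.5, shadow = 1) {
  nx <- round(extent_x / pitch); nz <- round(extent_z / pitch)
  cc <- spec@incl_center; r <- spec@incl_diameter / 2
  x_mm <- cc[1] + (seq_len(nx) - 1) * pitch - (nx - 1) / 2 * pitch
  z_mm <- (seq_len(nz) - 1) * pitch
  rho <- outer(x_mm, z_mm, function(x, z) sqrt((x - cc[1])^2 + (z - cc[3])^2))
  inside <- rho < r
  mean_map <- matrix(1, nx, nz)
  mean_map[inside] <- contrast
  if (rim_amp > 0)
    mean_map <- mean_map + rim_amp * exp(-(rho - r)^2 / (2 * rim_width^2))
  if (shadow < 1) {
    band <- outer(x_mm, z_mm, function(x, z) abs(x - cc[1]) < r & z > cc[3] + r)
    mean_map[band] <- mean_map[band] * shadow
  }
  k <- gaussKernel1D(grain)
  smoothUnit <- function(m) {
    s <- convAxis(convAxis(m, k, 1), k, 2)
    s / stats::sd(s)
  }
  speckle <- 0
  for (l in seq_len(looks)) {
    g1 <- smoothUnit(matrix(stats::rnorm(nx * nz), nx, nz))
    g2 <- smoothUnit(matrix(stats::rnorm(nx * nz), nx, nz))
    speckle <- speckle + (g1^2 + g2^2) / 2
  }
  img <- usImage(mean_map * speckle / looks, pitch, origin = c(x_mm[1], 0))
  truth <- planarMask(inside, pitch, origin = c(x_mm[1], 0))
  list(image = img, truth = truth)
}
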