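## End-to-end reconstruction pipeline: windowing of measured data, the
## ultrasound-derived structural prior, the regularized inversion, and the
## five-contrast synthetic phantom sweep used for validation.

#' Window an area-normalized TPSF set into the stacked data vector
#'
#' Area-normalizes every pair's curve over the axis ROI, integrates it over
#' the temporal windows, and stacks the results pair-major (windows of a
#' pair contiguous) to match the row order of [assembleSystem()].
#'
#' @param set a [TPSFSet-class]
#' @param scheme a [WindowScheme-class]
#' @return list with `y` (stacked window integrals) and `sigma` (propagated
#'   standard deviations)
#' @export
windowedVector <- function(set, scheme) {
  npair <- nrow(set@values)
  k <- nWindows(scheme)
  y <- numeric(npair * k); sig <- numeric(npair * k)
  for (p in seq_len(npair)) {
    bw <- binWindows(normalizeArea(tpsfAt(set, p)), scheme)
    idx <- (p - 1) * k + seq_len(k)
    y[idx] <- bw$values
    sig[idx] <- bw$sigma
  }
  list(y = y, sigma = sig)
}

#' Build the ultrasound structural prior for a grid
#'
#' Runs the scale-space snake segmentation on a B-mode image, extrudes the
#' planar mask into a 3D characteristic volume on the reconstruction grid,
#' and returns the edge-weighting field and regularization operator.
#'
#' @param image a [USImage-class]
#' @param seeds seed points (n x 2 pixel coordinates), passed to
#'   [segmentLesion()]
#' @param grid a [VoxelGrid-class]
#' @param beta edge threshold for [gammaField()] (NULL = automatic)
#' @param ... further arguments to [segmentLesion()]
#' @return list with `mask` ([PlanarMask-class]), `chi` ([VolumeMask-class]),
#'   `gamma` ([EdgeWeightField-class]) and `L` (sparse operator)
#' @export
usPrior <- function(image, seeds, grid, beta = NULL, ...) {
  mask <- segmentLesion(image, seeds, ...)
  chi <- extrudeMask(mask, grid)
  gam <- gammaField(chi, beta = beta)
  list(mask = mask, chi = chi, gamma = gam, L = buildRegularizer(gam))
}

#' Reconstruct perturbations from measured and reference data
#'
#' Difference-data Born inversion: forms b = y - y_ref scaled by the
#' combined noise, and solves the regularized system with LSQR. `mode`
#' selects zeroth-order Tikhonov (identity operator), the edge-weighted
#' first-order prior (requires `L`), or no regularization.
#'
#' @param system a [SystemMatrix-class]
#' @param y,y_ref stacked windowed data vectors (see [windowedVector()])
#' @param sigma per-entry standard deviation of the difference b
#' @param mode one of "edge", "tikhonov0", "none"
#' @param L sparse regularizer from [buildRegularizer()] (edge mode)
#' @param alpha regularization weight or "auto"
#' @param alpha_factor automatic-weight multiplier
#' @param max_iter LSQR iteration cap
#' @return a [ReconstructionResult-class]
#' @export
reconstruct <- function(system, y, y_ref, sigma, mode = c("edge", "tikhonov0", "none"),
                        L = NULL, alpha = "auto", alpha_factor = 10,
                        max_iter = 100) {
  mode <- match.arg(mode)
  dd <- differenceData(y, y_ref, sigma)
  if (mode == "edge") {
    if (is.null(L)) stop("reconstruct: edge mode needs the prior operator L")
  } else L <- NULL
  if (mode == "none") alpha <- 0
  solveSystem(system, dd$S, dd$b, L = L, alpha = alpha,
              alpha_factor = alpha_factor, max_iter = max_iter)
}

## seed points for the synthetic phantom image: a ring just inside the
## true inclusion border (emulating the prescribed user interaction)
defaultSeeds <- function(truth_spec, image, n = 8, inset = 1) {
  cc <- truth_spec@incl_center; r <- truth_spec@incl_diameter / 2 - inset
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  x_mm <- cc[1] + r * cos(ang)
  z_mm <- cc[3] + r * sin(ang)
  cbind((x_mm - image@origin[1]) / image@pitch + 1,
        (z_mm - image@origin[2]) / image@pitch + 1)
}

#' Five-contrast synthetic phantom sweep
#'
#' Full synthetic twin of the phantom validation: for each nominal
#' absorption contrast NC (inclusion over bulk), simulates the
#' dual-phantom time-resolved measurements, reconstructs with both
#' zeroth-order Tikhonov and the ultrasound edge-weighting prior, and
#' tabulates the reconstructed contrast RC and localization metrics.
#' The ultrasound image, its segmentation and the system matrix are shared
#' across contrasts (the acoustic scene does not depend on the optical
#' contrast).
#'
#' @param nc_values nominal contrasts (default 0.5, 1, 2, 4, 6 relative to
#'   the 0.01 mm^-1 bulk)
#' @param counts detected photons per pair
#' @param seed RNG seed for the Poisson noise and speckle (NULL = leave RNG
#'   state alone)
#' @param grid reconstruction grid
#' @param axis time axis
#' @param alpha_factor automatic regularization weight multiplier
#' @param max_iter LSQR iteration cap per solve
#' @param verbose print progress?
#' @return data.frame, one row per (contrast, regularizer): columns include
#'   nc, mode, rc, d (centroid displacement, mm), mean_in, n_omega
#' @export
contrastSweep <- function(nc_values = c(0.5, 1, 2, 4, 6), counts = 1e6,
                          seed = NULL, grid = voxelGrid(), axis = timeAxis(25, 164),
                          alpha_factor = 10, max_iter = 100, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  bg <- opticalBackground(0.01, 1)
  layout <- defaultProbeLayout()
  geom <- slabGeometry(40, bg)
  base_spec <- phantomSpec(mu_a_in = bg@mu_a)

  ## temporal ROI and windows from the noiseless reference model
  irf <- makeIRF(250, axis)
  ref_model <- forwardTPSFSet(layout, bg, geom, axis, irf = irf)
  axis <- selectROI(ref_model, axis)
  scheme <- windowScheme(axis, 20)

  if (verbose) message("assembling system matrix ...")
  system <- assembleSystem(layout, grid, bg, geom, axis, scheme, irf = irf)

  if (verbose) message("segmenting synthetic B-mode image ...")
  us <- synthUSImage(base_spec)
  seeds <- defaultSeeds(base_spec, us$image)
  prior <- usPrior(us$image, seeds, grid)

  rows <- list()
  for (nc in nc_values) {
    spec <- phantomSpec(mu_a_in = nc * bg@mu_a)
    sim <- simulateMeasurements(spec, layout, axis, counts = counts)
    wy <- windowedVector(sim$y, scheme)
    wr <- windowedVector(sim$y_ref, scheme)
    sig <- sqrt(wy$sigma^2 + wr$sigma^2)
    truth <- list(centroid = spec@incl_center, mu_a_in = spec@incl_mu_a,
                  mu_a_bulk = bg@mu_a)
    for (mode in c("tikhonov0", "edge")) {
      res <- reconstruct(system, wy$y, wr$y, sig, mode = mode,
                         L = prior$L, alpha_factor = alpha_factor,
                         max_iter = max_iter)
      om <- localizeRegion(deltaMuA(res))
      met <- regionMetrics(deltaMuA(res), om, grid, bg@mu_a, truth)
      met$mode <- mode
      met$alpha <- res@alpha
      rows[[length(rows) + 1]] <- met
      if (verbose)
        message(sprintf("NC = %.2g %-9s RC = %6.3f d = %5.2f mm (|omega| = %d)",
                        met$nc, mode, met$rc, met$d, met$n_omega))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "system_dim") <- dim(system@J)
  attr(out, "prior_mask") <- prior$mask
  out
}
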