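## A two-position mini layout keeps kernel tests cheap
miniLayout <- function() {
  pos <- cbind(x = c(-6, 6), y = c(0, 0), z = 0)
  pr <- as.matrix(expand.grid(source = 1:2, detector = 1:2))
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  new("ProbeLayout", sources = pos, detectors = pos, pairs = pr)
}

test_that("Fourier-domain kernels equal direct time-domain convolution", {
  bg <- fix_bg(); geom <- fix_geom(bg)
  fs <- fix_short()
  vox <- c(3, 2, 10)
  sens <- sensitivityAbsorption(c(-18, -10, 0), c(6, 10, 0), vox, 8, bg, geom,
                                fs$axis, fs$scheme)
  tt <- timePoints(fs$axis)
  phi_s <- greenSlab(vox, c(-18, -10, 1), tt, bg, geom)
  phi_d <- greenSlab(vox, c(6, 10, 1), tt, bg, geom)
  ker <- -8 * usdot:::convolveDiscrete(phi_s, phi_d, fs$axis@dt)
  direct <- binWindows(tpsf(ker, fs$axis), fs$scheme)$values
  expect_lt(max(abs(sens - direct)) / max(abs(direct)), 1e-8)
})

test_that("absorption sensitivity is non-positive and decays far from the optodes", {
  bg <- fix_bg(); geom <- fix_geom(bg); fs <- fix_short()
  near <- sensitivityAbsorption(c(-6, 0, 0), c(6, 0, 0), c(0, 0, 10), 8,
                                bg, geom, fs$axis, fs$scheme)
  far <- sensitivityAbsorption(c(-6, 0, 0), c(6, 0, 0), c(60, 0, 10), 8,
                               bg, geom, fs$axis, fs$scheme)
  expect_true(all(near <= 1e-30))
  expect_lt(max(abs(far)), 1e-6 * max(abs(near)))
})

test_that("analytic gradients match finite differences (diffusion kernel oracle)", {
  bg <- fix_bg(); geom <- fix_geom(bg); fs <- fix_short()
  vox <- c(2, 1, 9); h <- 1e-3
  src <- c(-6, 0, 0); det <- c(6, 0, 0)
  sens <- sensitivityDiffusion(src, det, vox, 8, bg, geom, fs$axis, fs$scheme)

  ## oracle: numerical central-difference gradients of the slab fields,
  ## convolved and windowed in the time domain
  tt <- timePoints(fs$axis)
  gfd <- function(opt, comp) {
    e <- numeric(3); e[comp] <- h
    (greenSlab(vox + e, c(opt[1], opt[2], 1), tt, bg, geom) -
     greenSlab(vox - e, c(opt[1], opt[2], 1), tt, bg, geom)) / (2 * h)
  }
  ker <- numeric(fs$axis@n_t)
  for (comp in 1:3)
    ker <- ker + usdot:::convolveDiscrete(gfd(src, comp), gfd(det, comp), fs$axis@dt)
  direct <- binWindows(tpsf(-8 * ker, fs$axis), fs$scheme)$values
  expect_lt(max(abs(sens - direct)) / max(abs(direct)), 1e-4)
})

test_that("voxel quadrature of a Jacobian column converges under refinement", {
  bg <- fix_bg(); geom <- fix_geom(bg); fs <- fix_short()
  src <- c(-6, 0, 0); det <- c(6, 0, 0)
  vox <- c(1, 0, 11)                          # mid-depth 2 mm voxel center
  dmu <- 1e-4
  ## 4x finer one-point quadrature over the same voxel (the oracle)
  off <- seq(-0.75, 0.75, by = 0.5)
  sub <- as.matrix(expand.grid(vox[1] + off, vox[2] + off, vox[3] + off))
  fine <- colSums(sensitivityAbsorption(src, det, sub, 0.5^3, bg, geom,
                                        fs$axis, fs$scheme)) * dmu
  ## 2x2x2 Gauss nodes agree with the refined quadrature to < 1%
  g1 <- 1 / sqrt(3)
  gsub <- as.matrix(expand.grid(vox[1] + c(-g1, g1), vox[2] + c(-g1, g1),
                                vox[3] + c(-g1, g1)))
  gauss <- colSums(sensitivityAbsorption(src, det, gsub, 1, bg, geom,
                                         fs$axis, fs$scheme)) * dmu
  expect_lt(max(abs(gauss - fine)) / max(abs(fine)), 0.01)
  ## the fast center rule carries a few-percent single-voxel error on the
  ## steep rising-edge windows (the documented tractability tradeoff)
  coarse <- sensitivityAbsorption(src, det, vox, 8, bg, geom, fs$axis, fs$scheme) * dmu
  expect_lt(max(abs(coarse - fine)) / max(abs(fine)), 0.08)
})

test_that("assembled system has the contracted layout, reciprocity and linearity", {
  bg <- fix_bg(); geom <- fix_geom(bg); fs <- fix_short()
  lay <- miniLayout()
  grid <- voxelGrid(c(16, 12, 12), 4)
  sys <- assembleSystem(lay, grid, bg, geom, fs$axis, fs$scheme)
  n <- nVoxels(grid); k <- nWindows(fs$scheme)
  expect_identical(dim(sys@J), as.integer(c(nrow(lay@pairs) * k, 2 * n)))
  ## row order: source-major, then detector, then window
  expect_identical(sys@row_meta$window[1:k], 1:k)
  expect_identical(sys@row_meta$source, rep(lay@pairs[, 1], each = k))

  ## reciprocity: rows of (1 -> 2) equal rows of (2 -> 1)
  p12 <- which(lay@pairs[, 1] == 1 & lay@pairs[, 2] == 2)
  p21 <- which(lay@pairs[, 1] == 2 & lay@pairs[, 2] == 1)
  rs <- function(p) ((p - 1) * k + 1):(p * k)
  expect_identical(sys@J[rs(p12), ], sys@J[rs(p21), ])

  ## linearity and voxel-volume scaling
  set.seed(3)
  d1 <- rnorm(2 * n); d2 <- rnorm(2 * n)
  expect_equal(as.numeric(sys@J %*% (2 * d1 - 3 * d2)),
               as.numeric(2 * (sys@J %*% d1) - 3 * (sys@J %*% d2)), tolerance = 1e-12)
  s8 <- sensitivityAbsorption(c(-6, 0, 0), c(6, 0, 0), c(0, 0, 8), 8,
                              bg, geom, fs$axis, fs$scheme)
  s16 <- sensitivityAbsorption(c(-6, 0, 0), c(6, 0, 0), c(0, 0, 8), 16,
                               bg, geom, fs$axis, fs$scheme)
  expect_equal(s16, 2 * s8, tolerance = 1e-12)

  ## memory guard
  expect_error(assembleSystem(lay, voxelGrid(c(400, 400, 200), 1), bg, geom,
                              fs$axis, fs$scheme, max_gb = 0.5), "GiB")
})

test_that("normalized rows are the differential of the area-normalized signal", {
  ## J(normalized) applied to a homogeneous absorption step reproduces the
  ## difference of two normalized analytic models over an extended grid that
  ## includes the extrapolated-boundary margins
  bg <- fix_bg(); geom <- fix_geom(bg)
  ax <- fix_axis()
  irf <- makeIRF(250, ax)
  lay <- miniLayout()
  ax <- selectROI(forwardTPSFSet(lay, bg, geom, ax, irf = irf), ax)
  sch <- windowScheme(ax, 10)
  zb <- geom@z_b
  grid <- new("VoxelGrid", origin = c(-35, -31, -zb + 1), voxel = 2,
              dims = c(36, 32, 23))
  sys <- assembleSystem(lay, grid, bg, geom, ax, sch, irf = irf, max_gb = 7)
  eps <- 1e-5
  n <- nVoxels(grid); k <- nWindows(sch)
  pred <- as.numeric(sys@J[, seq_len(n)] %*% rep(eps, n))
  m1 <- forwardTPSFSet(lay, bg, geom, ax, irf = irf)
  m2 <- forwardTPSFSet(lay, opticalBackground(bg@mu_a + eps, 1), geom, ax, irf = irf)
  obs <- numeric(nrow(lay@pairs) * k)
  for (p in seq_len(nrow(lay@pairs))) {
    w1 <- binWindows(normalizeArea(tpsf(m1[p, ], ax)), sch)$values
    w2 <- binWindows(normalizeArea(tpsf(m2[p, ], ax)), sch)$values
    obs[(p - 1) * k + seq_len(k)] <- w2 - w1
  }
  expect_lt(max(abs(pred - obs)) / max(abs(obs)), 0.01)
  ## normalized rows of each pair sum to zero across windows
  rows1 <- colSums(matrix(sys@J[1:k, 1], nrow = k))
  expect_lt(abs(sum(sys@J[1:k, 17])) , 1e-12 * max(abs(sys@J[1:k, 17])))
})
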