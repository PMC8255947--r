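test_that("difference data scales by the noise and floors degenerate sigmas", {
  y <- c(1, 2, 3); s <- c(0.5, 0.5, 0.5)
  dd0 <- differenceData(y, y, s)
  expect_identical(dd0$b, c(0, 0, 0))
  dd1 <- differenceData(y, c(0, 0, 0), s)
  dd2 <- differenceData(y, c(0, 0, 0), 2 * s)
  expect_equal(dd2$b_scaled, dd1$b_scaled / 2)
  expect_warning(dd3 <- differenceData(y, c(0, 0, 0), c(0.5, 0, 0.5)), "floored")
  expect_true(all(is.finite(dd3$b_scaled)))
})

test_that("noise-scaled null differences have unit variance (Poisson pairs)", {
  ## two measurements of the same bulk: S (y - y_ref) should be ~N(0, 1)
  set.seed(9)
  spec0 <- phantomSpec(mu_a_in = 0.01)         # zero contrast
  lay <- defaultProbeLayout()
  ax <- fix_axis(); bg <- fix_bg()
  irf <- makeIRF(250, ax)
  ax <- selectROI(forwardTPSFSet(lay, bg, fix_geom(bg), ax, irf = irf), ax)
  sch <- windowScheme(ax, 20)
  zs <- c()
  for (r in 1:6) {
    sim <- simulateMeasurements(spec0, lay, ax, counts = 1e5)
    wy <- windowedVector(sim$y, sch); wr <- windowedVector(sim$y_ref, sch)
    dd <- differenceData(wy$y, wr$y, sqrt(wy$sigma^2 + wr$sigma^2))
    zs <- c(zs, dd$b_scaled)
  }
  expect_gt(sd(zs), 0.85); expect_lt(sd(zs), 1.1)
})

test_that("LSQR matches the dense normal equations and is exactly zero on b = 0", {
  set.seed(10)
  J <- matrix(rnorm(4 * 6), 4, 6)
  ## zero right-hand side
  z <- lsqrSolve(function(x) J %*% x, function(y) crossprod(J, y), numeric(4), 6)
  expect_identical(z$x, numeric(6))

  ## tiny regularized system vs dense solve
  alpha <- 0.3; b <- rnorm(4)
  dense <- solve(crossprod(J) + alpha * diag(6), crossprod(J, b))
  sol <- lsqrSolve(function(x) c(J %*% x, sqrt(alpha) * x),
                   function(y) as.numeric(crossprod(J, y[1:4])) + sqrt(alpha) * y[5:10],
                   c(b, numeric(6)), 6, max_iter = 200, atol = 1e-14)
  expect_lt(max(abs(sol$x - as.numeric(dense))), 1e-8)
})

test_that("solveSystem honors the regularization modes on a 3-voxel toy system", {
  set.seed(11)
  grid <- new("VoxelGrid", origin = c(0, 0, 1), voxel = 1, dims = c(3, 1, 1))
  n <- 3
  J <- matrix(rnorm(4 * 6), 4, 6)
  sys <- new("SystemMatrix", J = J,
             row_meta = data.frame(source = 1:4, detector = 1, window = 1),
             grid = grid, model = matrix(1, 4, 1), normalized = FALSE)
  b <- rnorm(4); S <- rep(1, 4)

  ## zeroth-order Tikhonov vs the dense oracle at the same alpha
  res <- solveSystem(sys, S, b, alpha = 0.3, max_iter = 300, atol = 1e-14)
  dense <- solve(crossprod(J) + 0.3 * diag(6), crossprod(J, b))
  expect_lt(max(abs(c(deltaMuA(res), deltaKappa(res)) - as.numeric(dense))), 1e-8)

  ## alpha = 0 without L reduces to plain least squares
  res0 <- solveSystem(sys, S, b, alpha = 0, max_iter = 300, atol = 1e-14)
  sv <- svd(J)                               # minimum-norm least-squares solution
  lsq <- sv$v %*% ((crossprod(sv$u, b)) / sv$d)
  expect_lt(max(abs(c(deltaMuA(res0), deltaKappa(res0)) - as.numeric(lsq))), 1e-6)

  ## solution norm is non-increasing along an alpha sweep
  norms <- vapply(c(1e-2, 1e-1, 1, 10), function(a) {
    r <- solveSystem(sys, S, b, alpha = a, max_iter = 300, atol = 1e-14)
    sqrt(sum(deltaMuA(r)^2) + sum(deltaKappa(r)^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-12))

  ## a first-order L (N columns) is applied to both coefficient blocks
  L <- buildRegularizer(array(1, c(3, 1, 1)), grid)
  resL <- solveSystem(sys, S, b, L = L, alpha = 0.5, max_iter = 300, atol = 1e-14)
  Lb <- as.matrix(Matrix::bdiag(L, L))
  denseL <- solve(crossprod(J) + 0.5 * crossprod(Lb), crossprod(J, b))
  expect_lt(max(abs(c(deltaMuA(resL), deltaKappa(resL)) - as.numeric(denseL))), 1e-8)
})

test_that("region localization uses the 4-sigma rule and recovers a blob", {
  expect_false(any(localizeRegion(array(3, c(5, 5, 5)))))

  set.seed(12)
  field <- array(rnorm(10000), c(25, 25, 16))
  blob <- array(FALSE, dim(field)); blob[10:12, 10:13, 5:8] <- TRUE  # 48 voxels
  field[blob] <- 20
  om <- localizeRegion(field)
  expect_gte(sum(om & blob) / sum(blob), 0.95)
  expect_lte(sum(om & !blob), 5)
  ## default threshold is 4
  expect_identical(formals(localizeRegion)$threshold, 4)
})

test_that("region metrics reproduce the identity case and voxel-pitch displacement", {
  grid <- voxelGrid()
  cen <- voxelCenters(grid)
  truth_center <- c(0, 0, 10.5)
  incl <- (cen[, 1])^2 + (cen[, 3] - truth_center[3])^2 <= 5.5^2 & abs(cen[, 2]) <= 5
  field <- array(0, gridDims(grid))
  field[incl] <- -3.8e-3                       # true perturbation of the low-contrast case
  om <- array(incl, gridDims(grid))
  truth <- list(centroid = truth_center, mu_a_in = 0.0037, mu_a_bulk = 0.0075)
  met <- regionMetrics(field, om, grid, 0.0075, truth)
  expect_equal(met$mean_in, -3.8e-3)
  expect_equal(met$integral_in, -3.8e-3 * sum(incl) * voxelVolume(grid))
  expect_lt(met$d, 0.5)                        # voxelized centroid vs true center
  expect_equal(met$rc, met$nc, tolerance = 0.02)
  expect_equal(met$nc, 0.0037 / 0.0075)
  ## bounding-box elongations on this 2 mm grid registration (voxel centers
  ## at odd x/z coordinates, so the z = 5 boundary plane holds no centers)
  expect_equal(met$dx, 12); expect_equal(met$dy, 10); expect_equal(met$dz, 10)

  ## shifting omega by one voxel in z moves the centroid by the pitch
  om2 <- array(FALSE, gridDims(grid))
  om2[, , 2:gridDims(grid)[3]] <- om[, , 1:(gridDims(grid)[3] - 1)]
  uniform <- array(1, gridDims(grid))
  m1 <- regionMetrics(uniform, om, grid, 0.01, truth)
  m2 <- regionMetrics(uniform, om2, grid, 0.01, truth)
  expect_equal(m2$z - m1$z, grid@voxel)

  ## empty region flags metrics as undefined
  met0 <- regionMetrics(field, array(FALSE, gridDims(grid)), grid, 0.01, truth)
  expect_true(is.na(met0$mean_in) && is.na(met0$rc))
})
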