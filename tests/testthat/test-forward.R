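test_that("infinite-space Green's function has the closed form, causality and conservation", {
  bg <- fix_bg()
  ## peak value at coincident points with zero absorption
  bg0 <- opticalBackground(0, 1)
  t0 <- 500
  expect_equal(greenInfinite(c(1, 2, 3), c(1, 2, 3), t0, bg0),
               bg0@v * (4 * pi * bg0@v * bg0@kappa * t0)^(-1.5))
  ## causality
  expect_identical(greenInfinite(c(1, 0, 0), c(0, 0, 0), c(-10, 0), bg), c(0, 0))
  expect_error(greenInfinite(c(NA, 0, 0), c(0, 0, 0), 1, bg), "non-finite")

  ## conservation oracle: integral of G over R^3 = v * exp(-mu_a v t),
  ## trapezoid quadrature on a grid spanning +-10 sqrt(2 kappa v t)
  for (t0 in c(200, 500, 1500)) {
    L <- 10 * sqrt(2 * bg@kappa * bg@v * t0)
    xs <- seq(-L, L, length.out = 61)
    h <- xs[2] - xs[1]
    w <- rep(1, 61); w[c(1, 61)] <- 0.5       # trapezoid weights
    g1 <- exp(-xs^2 / (4 * bg@kappa * bg@v * t0))
    int1 <- sum(w * g1) * h                   # separable Gaussian factor
    int3 <- int1^3 * bg@v * (4 * pi * bg@v * bg@kappa * t0)^(-1.5) *
      exp(-bg@mu_a * bg@v * t0)
    expect_lt(abs(int3 - bg@v * exp(-bg@mu_a * bg@v * t0)) /
              (bg@v * exp(-bg@mu_a * bg@v * t0)), 0.005)
  }
})

test_that("the Green's function satisfies the diffusion equation away from the source", {
  bg <- fix_bg()
  r1 <- c(0, 0, 0); r2 <- c(6, 3, 4); t0 <- 600
  hs <- 1e-2; ht <- 1e-1
  g <- function(p, t) greenInfinite(p, r1, t, bg)
  lap <- sum(vapply(1:3, function(d) {
    e <- numeric(3); e[d] <- hs
    g(r2 + e, t0) + g(r2 - e, t0) - 2 * g(r2, t0)
  }, 0)) / hs^2
  dt_ <- (g(r2, t0 + ht) - g(r2, t0 - ht)) / (2 * ht)
  resid <- dt_ / bg@v - bg@kappa * lap + bg@mu_a * g(r2, t0)
  expect_lt(abs(resid), 1e-3 * abs(g(r2, t0)) )
})

test_that("slab Green's function respects the extrapolated boundaries and image convergence", {
  bg <- fix_bg(); geom <- fix_geom(bg)
  tt <- seq(25, 4000, by = 25)
  ## fluence at the extrapolated plane z = -z_b is tiny vs an interior value
  interior <- greenSlab(c(0, 0, 10), c(0, 0, 1), tt, bg, geom)
  ## evaluate the image series at the extrapolated plane directly
  img <- usdot:::imageSourceTable(1, geom)
  at_plane <- Reduce(`+`, lapply(seq_len(nrow(img)), function(i)
    img$sign[i] * greenInfinite(c(0, 0, -geom@z_b), c(0, 0, img$z[i]), tt, bg)))
  expect_lt(max(abs(at_plane)), 1e-3 * max(interior))

  ## semi-infinite limit equals the explicit two-term dipole
  geom_inf <- slabGeometry(Inf, bg)
  v1 <- greenSlab(c(5, 2, 8), c(0, 0, 1), tt, bg, geom_inf)
  v2 <- greenInfinite(c(5, 2, 8), c(0, 0, 1), tt, bg) -
        greenInfinite(c(5, 2, 8), c(0, 0, -2 * geom_inf@z_b - 1), tt, bg)
  expect_equal(v1, v2, tolerance = 1e-12)

  ## image-series convergence: 7 vs 15 dipole pairs
  g7 <- greenSlab(c(5, 3, 20), c(0, 0, 1), tt, bg, geom)
  g15 <- greenSlab(c(5, 3, 20), c(0, 0, 1), tt, bg, slabGeometry(40, bg, n_images = 15))
  expect_lt(max(abs(g7 - g15)) / max(abs(g15)), 1e-6)
})

test_that("model TPSFs are causal, reciprocal, and delay grows with separation", {
  bg <- fix_bg(); geom <- fix_geom(bg); ax <- fix_axis()
  seps <- c(12, 20, 23.3)
  mt <- vapply(seps, function(s) {
    curve <- forwardTPSF(c(0, 0, 0), c(s, 0, 0), bg, geom, ax)
    v <- tpsfValues(curve); tt <- timePoints(ax)
    sum(tt * v) / sum(v)                      # mean time of flight
  }, 0)
  expect_true(all(diff(mt) > 0))
  curve <- forwardTPSF(c(0, 0, 0), c(12, 0, 0), bg, geom, ax)
  expect_true(all(tpsfValues(curve) >= 0))
  expect_identical(tpsfValues(curve)[1], 0)   # t = 0 bin

  ## reciprocity is bit-exact
  a <- forwardTPSF(c(-18, -10, 0), c(6, 10, 0), bg, geom, ax)
  b <- forwardTPSF(c(6, 10, 0), c(-18, -10, 0), bg, geom, ax)
  expect_identical(tpsfValues(a), tpsfValues(b))

  ## zero-separation pairs are allowed but flagged
  expect_message(forwardTPSF(c(0, 0, 0), c(0, 0, 0), bg, geom, ax), "zero source-detector")
})

test_that("IRF convolution is the identity for a delta and conserves area", {
  bg <- fix_bg(); geom <- fix_geom(bg)
  ax <- fix_axis(640)                          # long axis so tails are negligible
  curve <- forwardTPSF(c(0, 0, 0), c(12, 0, 0), bg, geom, ax)
  delta <- tpsf(c(1 / ax@dt, numeric(ax@n_t - 1)), ax)   # unit-area discrete delta
  out <- convolveIRF(curve, delta)
  expect_equal(tpsfValues(out), tpsfValues(curve), tolerance = 1e-12)

  irf <- makeIRF(200, ax)
  out2 <- convolveIRF(curve, irf)
  a_in <- sum(tpsfValues(curve)) * ax@dt
  a_out <- sum(tpsfValues(out2)) * ax@dt
  expect_lt(abs(a_out - a_in) / a_in, 1e-10)
  expect_true(all(tpsfValues(out2) >= -1e-15 * max(tpsfValues(out2))))

  ## broadening: output FWHM at least the max of the input FWHMs
  fwhm <- function(v, tt) {
    top <- which(v >= max(v) / 2)
    tt[max(top)] - tt[min(top)]
  }
  tt <- timePoints(ax)
  expect_gte(fwhm(tpsfValues(out2), tt),
             max(fwhm(tpsfValues(curve), tt), fwhm(tpsfValues(irf), tt)))
  expect_error(convolveIRF(curve, makeIRF(200, fix_axis(128))), "mismatched")
})

test_that("area normalization is exact, scale invariant, and rejects empty curves", {
  ax <- fix_axis(64)
  set.seed(1)
  v <- runif(64)
  x <- tpsf(v, ax)
  nx <- normalizeArea(x)
  expect_lt(abs(sum(tpsfValues(nx)[ax@roi[1]:ax@roi[2]]) * ax@dt - 1), 1e-12)
  expect_equal(tpsfValues(normalizeArea(tpsf(7 * v, ax))), tpsfValues(nx))
  expect_equal(tpsfValues(normalizeArea(nx)), tpsfValues(nx))
  expect_error(normalizeArea(tpsf(numeric(64), ax)), "area")
})

test_that("window binning partitions the ROI exactly", {
  ax <- fix_axis(160)
  sch <- windowScheme(ax, 20)
  expect_identical(nWindows(sch), 20L)
  set.seed(2)
  x <- tpsf(runif(160), ax, sigma = runif(160))
  bw <- binWindows(x, sch)
  roi_int <- sum(tpsfValues(x)[ax@roi[1]:ax@roi[2]]) * ax@dt
  expect_lt(abs(sum(bw$values) - roi_int) / roi_int, 1e-10)

  ## constant curve, equal windows
  const <- tpsf(rep(3, 160), ax)
  bwc <- binWindows(const, sch)
  expect_equal(bwc$values, rep(3 * 160 * ax@dt / 20, 20), tolerance = 1e-12)

  ## propagated sigma of a window integral
  expect_equal(bw$sigma[1],
               ax@dt * sqrt(sum(x@sigma[which(usdot:::windowIndex(ax, sch) == 1)]^2)))

  bad <- new("WindowScheme", edges = c(-100, 50))
  expect_error(binWindows(x, bad), "outside")
})

test_that("ROI selection keeps the span where the reference exceeds the threshold", {
  ax <- fix_axis()
  v <- exp(-((timePoints(ax) - 1000) / 300)^2)
  ax2 <- selectROI(v, ax, frac = 0.01)
  keep <- which(v >= 0.01 * max(v))
  expect_identical(as.integer(ax2@roi), as.integer(range(keep)))
})
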