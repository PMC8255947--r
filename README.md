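# usdot

Ultrasound-guided time-domain diffuse optical tomography (TD-DOT)
reconstruction in R.

Diffuse optical tomography recovers maps of the optical absorption
coefficient μa (and diffusion coefficient κ) inside tissue from
near-infrared light injected and collected at the surface. The inverse
problem is severely ill-posed, so unaided reconstructions are blurry and
quantitatively biased. This package implements a reconstruction pipeline
for a dual-modality probe in which a concurrent B-mode ultrasound image
supplies a structural prior:

1. **Forward model.** Time-domain diffusion in a slab: the photon fluence
   Φ obeys (1/v) ∂Φ/∂t − ∇·κ∇Φ + μa Φ = q, solved analytically with the
   infinite-space Green's function
   G(r₂, r₁, t) = v (4πvκt)^(−3/2) exp(−|r₂−r₁|²/(4κvt)) exp(−μa v t)
   and the method of images for the slab's extrapolated boundaries. Model
   curves are convolved with the instrument response function,
   area-normalized, and integrated over N_TW temporal windows.
2. **Born Jacobian.** The windowed sensitivity of each source–detector
   pair to voxel perturbations δμa, δκ (temporal convolutions of the
   source fluence with the detector Green's function, evaluated by FFT),
   stacked into a matrix with N_Q·M·N_TW rows and 2N columns.
3. **Ultrasound prior.** A semi-automatic scale-space snake segments the
   lesion in the B-mode image (smoothed-Laplacian percentile features,
   squared-distance-transform potentials, user seed points); the planar
   mask χ_P is extruded to a 3D characteristic volume χ through the
   distance-transform height function y_ext² = 2·sqrt(A/π)·D − D², and an
   edge-weighting field γ = exp(−|∇χ|/β) relaxes the smoothness penalty
   across the prior's boundary.
4. **Inversion.** LSQR solution of the noise-scaled, edge-weighted
   first-order Tikhonov system
   ‖ (S J; α^{1/2} L) (δμa; δκ) − (S b; 0) ‖² → min,
   with b the windowed difference between the measurement and a
   homogeneous reference. Zeroth-order Tikhonov is available for
   comparison. The reconstructed inclusion is localized by a 4-σ rule and
   summarized by region metrics (mean δμa, centroid displacement,
   contrast RC vs the nominal contrast NC).
5. **Synthetic phantoms.** A generator reproduces the silicone dual-modality
   phantom study: a 40 mm bulk slab (μs′ = 1 mm⁻¹, μa = 0.01 mm⁻¹) with an
   11 mm × 10 mm cylindrical inclusion (≈950 mm³) under a 5 mm cover at
   nominal contrasts NC ∈ {0.5, 1, 2, 4, 6}, measured by an 8-position
   probe (two rows of four, 12 mm pitch, rows 20 mm apart → 64 pairs), plus
   speckled B-mode-like images of the anechoic inclusion.

## Worked example

```r
library(usdot)
set.seed(7)

spec   <- phantomSpec(mu_a_in = 0.04)          # NC = 4 phantom
layout <- defaultProbeLayout()
bg     <- opticalBackground(0.01, 1)
geom   <- slabGeometry(40, bg)
axis   <- timeAxis(25, 164)
irf    <- makeIRF(250, axis)

## temporal ROI + 20 windows from the homogeneous model
axis   <- selectROI(forwardTPSFSet(layout, bg, geom, axis, irf = irf), axis)
scheme <- windowScheme(axis, 20)

## system matrix, synthetic measurements, ultrasound prior
system <- assembleSystem(layout, voxelGrid(), bg, geom, axis, scheme, irf = irf)
sim    <- simulateMeasurements(spec, layout, axis)
us     <- synthUSImage(spec)
seeds  <- cbind(c(82, 76, 64, 52, 47, 52, 64, 76),
                c(42, 55, 60, 55, 42, 30, 24, 30))   # inside the lesion border
prior  <- usPrior(us$image, seeds, voxelGrid())

wy  <- windowedVector(sim$y, scheme)
wr  <- windowedVector(sim$y_ref, scheme)
sig <- sqrt(wy$sigma^2 + wr$sigma^2)
res <- reconstruct(system, wy$y, wr$y, sig, mode = "edge", L = prior$L)

omega <- localizeRegion(deltaMuA(res))
regionMetrics(deltaMuA(res), omega, voxelGrid(), 0.01,
              truth = list(centroid = c(0, 0, 10.5), mu_a_in = 0.04,
                           mu_a_bulk = 0.01))
```

Output (one run; the Poisson noise is seeded):

```
  n_omega    mean_in integral_in         x          y        z        d dx dy dz       rc nc
1     130 0.02175903    22.62939 -0.146092 -0.1866617 9.434616 1.091434 12 14 16 3.175705  4
```

The reconstructed contrast `rc` ≈ 3.2 against the nominal `nc` = 4 with a
centroid displacement `d` ≈ 1.1 mm; the same data reconstructed with
`mode = "tikhonov0"` give rc ≈ 1.8 and d ≈ 4.1 mm, the quantification gap
the structural prior is designed to close. A full five-contrast
comparison is one call: `contrastSweep(seed = 1)`.

A thin command-line front end (`inst/scripts/usdot`) exposes
`simulate`, `segment` and `reconstruct` subcommands over CSV/PNG/YAML
files.

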