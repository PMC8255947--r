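---
title: "Ultrasound-guided time-domain diffuse optical reconstruction: models and methods"
author: "usdot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound-guided time-domain diffuse optical reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the photon-transport model and its assumptions, the Born linearization,
the ultrasound-derived structural prior, the numerical choices made where
the design was genuinely open, what the synthetic phantom generator does
and does not emulate, and the known limitations.

## 1. The forward model and its assumptions

Light propagation is modelled by the time-dependent diffusion
approximation: the fluence $\Phi(\mathbf r, t)$ obeys

$$\frac{1}{v}\frac{\partial \Phi}{\partial t}
  - \nabla\cdot\kappa\nabla\Phi + \mu_a \Phi = q,$$

with absorption $\mu_a$ (mm$^{-1}$), diffusion coefficient
$\kappa = 1/(3\mu_s')$ (mm), and speed of light in the medium
$v = c_0/n$ (mm/ps). The diffusion approximation is accurate in
scattering-dominated media ($\mu_s' \gg \mu_a$, distances beyond a few
transport mean free paths) — amply satisfied by the silicone phantom
regime ($\mu_s' = 1$ mm$^{-1}$, $\mu_a \le 0.06$ mm$^{-1}$) the package
targets.

The homogeneous infinite-medium Green's function is the analytic Gaussian
kernel implemented by `greenInfinite()`; slab geometries are handled by
`greenSlab()` with the **extrapolated-boundary** method of images: the
fluence is forced to vanish on the virtual planes $z = -z_b$ and
$z = L + z_b$ by an alternating series of image dipoles, with
$z_b = 2\kappa(1+R_{\rm eff})/(1-R_{\rm eff})$ and $R_{\rm eff}$ from the
standard polynomial fit in the refractive index (`effectiveReflection()`;
$n = 1.54$ for silicone by default, configurable). Seven image dipole
pairs are retained; on a 40 mm slab within 4 ns the difference between 7
and 15 pairs is below $10^{-6}$ relative (the terms decay like
$e^{-(2L)^2/4\kappa v t}$), which the test suite verifies.

**Source/detector model.** The physical description gives only surface
positions. Following common time-domain practice, the source is an
isotropic point one transport mean free path $1/\mu_s'$ below the source
position and the measurement is the fluence sampled $1/\mu_s'$ below the
detector. This choice makes source–detector reciprocity exact by
construction (bit-for-bit in the tests). Zero-separation pairs (the 8
coincident pairs of the 64) are retained by default — the time-domain
kernel is finite for $t > 0$ — and flagged in a message because their
earliest bins are near-singular.

**Units.** mm, ps, mm$^{-1}$ throughout; $c_0 = 0.299792458$ mm/ps.

**Time sampling.** Curves are sampled at $t_i = i\,\Delta t$ (so the
$t = 0$ bin is exactly zero — causality is structural) with
$\Delta t = 25$ ps and 164 bins (4.1 ns) by default. Discrete
convolutions (IRF, Born kernels) are rectangle-rule sums times
$\Delta t$, evaluated on this common grid so that chained convolutions
stay exactly on-grid; window integrals are rectangle sums over the bins
belonging to each window, which makes the partition identity (sum of the
20 window integrals = ROI integral) exact to rounding.

**Temporal ROI and windows.** The analysis region of interest is, by
default, the span of bins where the pooled reference curve exceeds 1% of
its peak (`selectROI()`), standing in for the manual ROI selection of
practice; it is fully configurable. Twenty equally spaced windows
partition the ROI. The per-window noise level is the standard deviation
of the window integral, $\sigma_k = \Delta t\,(\sum_i \sigma_i^2)^{1/2}$;
with Poisson counting statistics this makes the noise-scaled null
difference $S(y - y_{\rm ref})$ unit-variance, which the test suite
checks empirically (a weighting-consistency requirement of the
Gaussian-noise objective the windows discretize).

## 2. The windowed Born Jacobian

Small perturbations $\delta\mu_a(\mathbf r')$, $\delta\kappa(\mathbf r')$
change the measurement, to first order, by the Born integrals: the
absorption kernel is the temporal convolution
$G^{(y)}(\mathbf r_d, \mathbf r', \cdot) \circledast
 \Phi(\mathbf r', \mathbf r_s, \cdot)$ and the diffusion kernel the
convolution of the dot product of the two spatial gradients, both with a
leading minus sign. Reciprocity lets the detector Green's function be
computed by placing a source at the detector. `assembleSystem()`
evaluates everything in the Fourier domain: fields for the eight optode
positions are FFT'd once per voxel block (zero-padded to at least twice
the axis length to avoid wrap-around), and the windowed, IRF-convolved
kernel integrals of all voxels of a pair reduce to one complex
matrix–matrix product against a precomputed $n_f \times N_{TW}$ window
operator that folds the IRF spectrum, the window indicators and all
rectangle-rule factors. Reciprocal pairs share blocks, so 64 ordered
pairs cost 36 unique evaluations. The result is a dense matrix with
$8 \times 8 \times 20 = 1280$ rows and $2N = 29696$ columns on the
default 64 × 58 × 32 mm grid of 2 mm voxels (assembled in about half a
minute); a memory guard refuses grids beyond a configurable budget.

**Voxel quadrature.** The default is a one-point (center) rule per voxel,
rationale: the diffuse kernels are several voxels wide, and in aggregate
the rule is excellent — a homogeneous absorption step pushed through the
Jacobian reproduces the closed-form derivative of the slab model to
$10^{-4}$ when the integration domain includes the extrapolated-boundary
margins $z \in [-z_b, 0]$ and $[L, L+z_b]$ (the image-series Green's
function carries its $e^{-\mu_a v t}$ factor over that whole virtual
domain; on the physical $z \ge 0$ grid the margins account for a ~3%
offset). For a *single* 2 mm voxel, however, the center rule misses the
kernel's curvature in the steep rising-edge windows by several percent.
`assembleSystem(quad_points = 2)` therefore offers a
$2\times2\times2$ Gauss rule (8× the field evaluations) whose
single-voxel columns agree with refined sub-voxel quadrature to well
below 1%; the validation suite uses it for the column-level oracle while
the large-scale sweep keeps the fast rule, whose per-column error is
bounded and documented in the tests.

**Area normalization.** Measured curves are normalized by area, which
destroys absolute intensity and makes the data sensitive only to curve
*shape*. The Jacobian rows are transformed accordingly into the
differential of the normalized windowed signal,
$\hat J_k = (J_k - \hat m_k \sum_l J_l)/A$, where $\hat m$ is the
normalized windowed model and $A$ its raw area. Each pair's transformed
rows sum to zero across windows, exactly as the normalized data
differences do.

## 3. The ultrasound prior

### Snake segmentation in scale-space

`segmentLesion()` implements the semi-automatic active-contour
procedure. The user supplies at least four seed points close to the
lesion border *on its inner side*. The filled seed polygon defines (i)
the repulsive potential (its squared interior distance, zero outside),
and (ii) the characteristic length $\hat r$ = its maximum interior
distance. At each of 15 scales, evenly spaced and descending from
$0.7\hat r$ to $0.15\hat r$, the image feature set is the lowest decile
of the Gaussian-smoothed 5-point Laplacian (unit-sum kernel, mirror
borders), the attraction potential is the squared exact Euclidean
distance to those features (`EBImage::distmap`), and the snake energy is
the arclength integral of the potential plus the internal bending energy
$\tfrac12\int a|C'|^2 + b|C''|^2\,d\ell$ with $a = 0$, $b = 1$ on the
periodic cubic spline through the control points. Minimization is
explicit gradient descent on the control points with finite-difference
gradients and backtracking step halving, accepting only
energy-decreasing steps (the recorded energy sequence is non-increasing
within a scale); each scale warm-starts from the previous contour,
arclength-resampled at scale transitions (resampling inside the
iteration would perturb the energy and break the monotonicity contract).
The final contour is filled (holes removed) into a binary planar mask.
There is no randomness anywhere in the optimizer: identical inputs give
bitwise-identical masks.

**Percentile convention.** The threshold is the 10th percentile of the
*signed* smoothed-Laplacian distribution (strictly-below, with ties
added in raster order); thresholding magnitudes instead is available as
`use_abs = TRUE`. The signed convention selects the strongly negative
band that bright rims and dark-to-bright transitions produce, which is
the behavior the rest of the procedure relies on.

**What the contour locks onto.** On images of a sharp anechoic inclusion
the strongest Laplacian response is the specular interface echo, whose
band straddles the true border; the recovered boundary is accurate to
about one pixel. For a pure intensity step with no rim, the negative
lobe sits a distance $\sigma$ *outside* the edge, so a residual outward
bias of order $\sigma_{\min}$ is intrinsic to the feature definition —
one reason the seeds are prescribed on the inner side.

### Extrusion and the edge weight

The planar mask is extruded by the distance-transform height function
$y_{\rm ext}^2 = 2 r D - D^2$ with $r = \sqrt{A/\pi}$ and $D$ the
interior distance field in mm: the extrusion vanishes at the boundary,
never exceeds the radius of the sphere whose middle section has the
mask's area, and maps a disk exactly onto that sphere. Discretely, $D$
is taken as (distance transform − ½ pixel) × pitch — the half-pixel
offset reads the transform as a pixel-center-to-continuum-boundary
distance, and brings the voxelized disk-to-sphere volume error to ~1.5%
at 1 mm pitch (6.6% without it). The volume is mirror-symmetric about
the imaging plane by construction.

The characteristic volume $\chi$ is smoothed with a 1-voxel Gaussian
(so the edge band spans about two voxels rather than aliasing onto
single faces), its gradient magnitude is taken by central differences,
and the edge weight is $\gamma = e^{-|\nabla\chi|/\beta}$. No value of
$\beta$ is prescribed by the method's description; the default is the
90th percentile of the nonzero gradient magnitudes, which puts
$\gamma \approx e^{-1}$ and below on the true edge band while leaving
flat regions at $\gamma = 1$. `buildRegularizer()` realizes
$R(f) = \sum \bar\gamma\,|\nabla f|^2\,V_{\rm vox}$ as a sparse
face-difference operator (three rows per voxel, Neumann far faces,
face-averaged $\gamma$), applied identically to the $\delta\mu_a$ and
$\delta\kappa$ blocks. Constants are in its null space; with
$\gamma \equiv 1$ it is the plain first-order Tikhonov operator.

## 4. Inversion

`solveSystem()` solves the stacked system
$\|(SJ;\ \alpha^{1/2}L)\,x - (Sb;\ 0)\|^2 \to \min$ with a
Paige–Saunders LSQR implementation on operator closures (deterministic,
starts at zero, so $b = 0$ returns exactly zero). Zeroth-order Tikhonov
substitutes the identity for $L$; $\alpha = 0$ with no $L$ is plain
least squares.

**Choosing $\alpha$.** No regularization weight is prescribed. The
automatic rule scales a user factor by
$\|SJ\|_F^2 / \|L\|_F^2$ so the factor is dimensionless and
grid-independent. The default factor is 10: at that weight the scaled
residual sits at the discrepancy-principle level for the synthetic
phantoms (the data misfit matches the known unit noise level), and the
solution is stable between 30 and 100 LSQR iterations. Much smaller
factors (e.g. $10^{-2}$) under-regularize: the minimum-norm bias then
concentrates the solution in the high-sensitivity voxels directly under
the optodes, for *both* regularizers, and the localized region collapses
to the surface. The iteration cap defaults to 100.

**Localization and contrast.** The reconstructed inclusion is the set
$\omega$ of voxels whose deviation from the median exceeds 4 standard
deviations (plain SD by default; MAD switchable). The reconstructed
contrast is RC = (bulk $\mu_a$ + mean $\delta\mu_a$ in $\omega$) /
(bulk $\mu_a$ + mean outside), compared with the nominal contrast NC.
Metrics are reported on $\delta\mu_a$; $\delta\kappa$ is co-reconstructed
(it absorbs scattering-mismatch artifacts) but not summarized.

## 5. The synthetic phantom generator

`simulateMeasurements()` builds the reference measurement from the
analytic slab model convolved with a unit-area Gaussian IRF, and the
inclusion measurement by adding the first-order Born perturbation of the
true cylinder, integrated over sub-voxels four times finer than the
reconstruction grid — the generator shares the *physics* (first-order
Born) with the reconstruction but not the discretization, a deliberately
mitigated inverse crime; a hook accepts externally generated curves for
stricter validation. Both curves are Poisson-sampled at $10^6$ detected
photons per pair (IRF FWHM 250 ps — plausible values for a
time-correlated single-photon-counting prototype; both are configurable
since count rates and response widths are instrument-specific) and carry propagated per-bin
standard deviations.

`synthUSImage()` emulates a zoomed B-mode scan of the phantom plane: a
32 × 20 mm window at 0.25 mm/pixel centered on the lesion (the decile
feature rule presumes the lesion border band is a non-negligible
fraction of the image, as it is in any clinically framed scan);
multiplicative squared-Rayleigh-family speckle with 4 incoherent looks
(display speckle contrast 0.5) and 1-pixel grain (~0.25 mm resolution
cells); the anechoic inclusion cross-section at mean intensity 0.25 of
the background; a specular interface echo along the inclusion boundary
(Gaussian cross-section, 0.5 mm half-width, peak twice the background
mean) — physically required by the acoustic impedance mismatch of the
two silicones and clearly visible in real scans of such phantoms; and an
optional posterior shadow band. The exact cross-section is returned as
ground truth. What the generator does **not** emulate: acoustic wave
propagation, depth-dependent attenuation/TGC, log-compression of the
display, refraction artifacts, or heterogeneous lesion interiors — so a
passing segmentation here shows the algorithm recovers a realistic
speckled anechoic target, not that it handles every clinical image.

## 6. Validation at a glance

The test suite ties every module to an independent oracle: photon
conservation and the PDE residual for the Green's function; bit-exact
reciprocity; image-series convergence; brute-force distance transforms;
dense normal-equation solves against LSQR; quadratic-form loops against
the sparse regularizer; closed-form disk-to-sphere extrusion; and the
five-contrast synthetic sweep, which shows the expected qualitative
behavior — correct perturbation sign at every contrast, and uniformly
better quantification (|RC − NC|) and localization (centroid
displacement ~1 mm vs ~4–6 mm) with the edge prior than with
zeroth-order Tikhonov. At zero true contrast (NC = 1) both regularizers
return RC within noise of 1, so the sign and inequality comparisons are
made over the contrasted cases only. Problem sizes in the routine tests
are scaled to what a laptop runs in minutes (the full 1280 × 29696
system is assembled once for the sweep; kernel-level oracles use
two-optode layouts and short axes); the simulation-based checks
(Poisson dispersion, null-variance) use hundreds rather than thousands
of repetitions, with seeds fixed.

## 7. Known limitations

- First-order Born linearization: quantification degrades at high
  contrast (RC ≈ 5.3 at NC = 6 even with the prior), the regime where a
  single linearization step is known to fall short.
- The analytic slab model assumes a laterally infinite, homogeneous
  background; curved or layered media are out of scope.
- The extrusion assumes the scan plane cuts the lesion's maximal
  cross-section and a smoothly decaying out-of-plane extent; strongly
  anisotropic lesions violate it (by design, the bound
  $y_{\rm ext} \le \sqrt{A/\pi}$ caps the damage).
- The snake's feature definition carries an outward localization bias of
  order the final smoothing scale when the lesion border lacks a
  specular rim.
- Single wavelength per run; spectral tissue-composition fitting is not
  included.
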