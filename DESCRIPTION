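Package: usdot
Title: Ultrasound-Guided Time-Domain Diffuse Optical Tomography Reconstruction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear (Born) reconstruction of absorption and diffusion
    perturbations from time-domain diffuse optical tomography measurements,
    regularized by an edge-weighting structural prior derived from a 2D
    ultrasound B-mode image. Provides an analytic time-domain diffusion
    forward model for slab geometries (method of images), windowed Born
    Jacobian assembly via Fourier-domain convolution, a semi-automatic
    scale-space snake segmentation of B-mode images, a distance-transform
    extrusion of the planar segmentation into a 3D characteristic volume,
    an edge-weighted first-order regularizer with LSQR inversion, and a
    synthetic dual-modality phantom generator (time-resolved photon
    histograms with Poisson noise plus speckled B-mode-like images) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RNifti,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, ImageReconstruction, Segmentation
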