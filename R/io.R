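## Plain-text interchange: TPSF sets as CSV with a YAML sidecar, masks as
## PNG, volumes as NIfTI (via RNifti, when installed), configuration as
## YAML.

#' Write a TPSF set to CSV (+ YAML sidecar)
#'
#' Long-format CSV with columns pair, bin, t, value, sigma; the time axis
#' and ROI go into `<file>.yaml`.
#'
#' @param set a [TPSFSet-class]
#' @param file CSV path
#' @export
writeTPSFSet <- function(set, file) {
  ax <- set@axis
  npair <- nrow(set@values)
  df <- data.frame(pair = rep(seq_len(npair), each = ax@n_t),
                   bin = rep(seq_len(ax@n_t), npair),
                   t = rep(timePoints(ax), npair),
                   value = as.vector(t(set@values)),
                   sigma = if (length(set@sigma)) as.vector(t(set@sigma)) else NA_real_)
  utils::write.csv(df, file, row.names = FALSE)
  yaml::write_yaml(list(t0 = ax@t0, dt = ax@dt, n_t = ax@n_t, roi = ax@roi),
                   paste0(file, ".yaml"))
}

#' Read a TPSF set written by [writeTPSFSet()]
#' @param file CSV path (expects `<file>.yaml` next to it)
#' @return a [TPSFSet-class]
#' @export
readTPSFSet <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  df <- utils::read.csv(file)
  ax <- timeAxis(meta$dt, meta$n_t, meta$t0, roi = unlist(meta$roi))
  npair <- max(df$pair)
  vals <- matrix(df$value, npair, ax@n_t, byrow = TRUE)
  sig <- if (all(is.na(df$sigma))) matrix(0, 0, 0)
         else matrix(df$sigma, npair, ax@n_t, byrow = TRUE)
  tpsfSet(vals, ax, sig)
}

#' Read a grayscale B-mode image from PNG (or TIFF)
#'
#' The pixel pitch comes from a `<file>.yaml` sidecar (`pitch` key) unless
#' given. Image files store depth (z) along rows; the returned object has
#' x along rows, z along columns.
#'
#' @param file PNG or TIFF path
#' @param pitch pixel pitch, mm/pixel (overrides the sidecar)
#' @return a [USImage-class]
#' @export
readUSImage <- function(file, pitch = NULL) {
  px <- if (grepl("\\.tiff?$", file, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package not installed")
    tiff::readTIFF(file)
  } else png::readPNG(file)
  if (length(dim(px)) == 3) px <- px[, , 1]
  if (is.null(pitch)) {
    side <- paste0(file, ".yaml")
    if (!file.exists(side)) stop("readUSImage: no pitch given and no YAML sidecar")
    pitch <- yaml::read_yaml(side)$pitch
  }
  usImage(t(px), pitch)
}

#' Write a planar mask as PNG (+ JSON metadata)
#' @param mask a [PlanarMask-class]
#' @param file PNG path
#' @export
writeMaskPNG <- function(mask, file) {
  png::writePNG(t(mask@mask), file)
  jsonlite::write_json(list(pitch = mask@pitch, origin = mask@origin,
                            area_mm2 = maskArea(mask)),
                       paste0(file, ".json"), auto_unbox = TRUE)
}

#' Write a characteristic volume (or any voxel field) as NIfTI
#' @param x a [VolumeMask-class], [EdgeWeightField-class] or 3D array
#' @param file output path (.nii or .nii.gz)
#' @param voxel voxel size, mm (taken from the object when available)
#' @export
writeVolumeNifti <- function(x, file, voxel = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti package not installed")
  arr <- if (is(x, "VolumeMask")) x@mask else if (is(x, "EdgeWeightField")) x@gamma else x
  if (is.null(voxel))
    voxel <- if (is(x, "VolumeMask") || is(x, "EdgeWeightField")) x@grid@voxel else 1
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- rep(voxel, 3)
  RNifti::writeNifti(img, file)
}

#' Read a phantom/acquisition configuration from YAML
#'
#' Keys (all optional, with package defaults): `bulk` (mu_a, mu_s_prime,
#' n_refr), `thickness`, `inclusion` (mu_a, mu_s_prime, diameter, height,
#' cover_depth), `axis` (dt, n_t), `counts`, `irf_fwhm`.
#'
#' @param file YAML path
#' @return list with `spec` ([PhantomSpec-class]), `axis`, `counts`, `irf_fwhm`
#' @export
readPhantomConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  bk <- cfg$bulk
  bg <- opticalBackground(mu_a = bk$mu_a %||% 0.01,
                          mu_s_prime = bk$mu_s_prime %||% 1,
                          n_refr = bk$n_refr %||% 1.54)
  inc <- cfg$inclusion
  spec <- phantomSpec(mu_a_in = inc$mu_a %||% 0.02, bulk = bg,
                      thickness = cfg$thickness %||% 40,
                      cover_depth = inc$cover_depth %||% 5,
                      diameter = inc$diameter %||% 11,
                      height = inc$height %||% 10,
                      mu_s_prime_in = inc$mu_s_prime %||% 1)
  ax <- timeAxis(cfg$axis$dt %||% 25, cfg$axis$n_t %||% 164)
  list(spec = spec, axis = ax, counts = cfg$counts %||% 1e6,
       irf_fwhm = cfg$irf_fwhm %||% 250)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
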