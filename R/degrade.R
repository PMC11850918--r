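#' Forward-model degradation parameters
#'
#' Parameterizes the LSFM image-formation model used by the simulator:
#' anisotropic Gaussian PSF blur (light-sheet optics: lateral resolution
#' finer than axial), additive long-range scattering haze obtained by
#' convolving the signal with a wide Gaussian kernel, and photon-limited
#' Poisson-Gaussian (sCMOS) noise.
#'
#' Default PSF sigmas correspond to 0.98 um lateral / 4 um axial FWHM
#' (sigma = FWHM / 2.355), the resolution of a 20x light-sheet detection
#' path.
#'
#' @param lateral_sigma_um PSF sigma in y/x (um), `> 0`.
#' @param axial_sigma_um PSF sigma in z (um), `> 0`; by light-sheet
#'   convention `>= lateral_sigma_um`.
#' @param haze_strength scattered-light amplitude relative to the ballistic
#'   signal, `>= 0`.
#' @param haze_kernel_sigma_um width of the scattering kernel (um), `> 0`;
#'   much wider than the PSF.
#' @param confocal_rejection residual fraction of haze passed by the
#'   detection scheme: 1 = conventional LSFM (full haze), 0 = ideal
#'   line-confocal rejection.
#' @param photon_gain expected photons collected at unit intensity, `> 0`
#'   (the light-dose knob).
#' @param read_sigma Gaussian read-noise sd in intensity units, `>= 0`.
#' @param background_offset constant detection background, `>= 0`.
#' @return A `degradation_params` list.
#' @export
degradation_params <- function(lateral_sigma_um = 0.98 / 2.355,
                               axial_sigma_um = 4 / 2.355,
                               haze_strength = 1.0,
                               haze_kernel_sigma_um = 10,
                               confocal_rejection = 1.0,
                               photon_gain = 100,
                               read_sigma = 0.01,
                               background_offset = 0.0) {
  stopifnot_scalar_num(lateral_sigma_um, "lateral_sigma_um", min = 1e-9)
  stopifnot_scalar_num(axial_sigma_um, "axial_sigma_um", min = 1e-9)
  stopifnot_scalar_num(haze_strength, "haze_strength", min = 0)
  stopifnot_scalar_num(haze_kernel_sigma_um, "haze_kernel_sigma_um", min = 1e-9)
  stopifnot_scalar_num(confocal_rejection, "confocal_rejection", 0, 1)
  if (!(is.numeric(photon_gain) && length(photon_gain) == 1L &&
        (is.infinite(photon_gain) || (is.finite(photon_gain) && photon_gain > 0))))
    stop("`photon_gain` must be a positive number (Inf = noiseless limit)",
         call. = FALSE)
  stopifnot_scalar_num(read_sigma, "read_sigma", min = 0)
  stopifnot_scalar_num(background_offset, "background_offset", min = 0)
  if (lateral_sigma_um > axial_sigma_um)
    warning("lateral_sigma_um > axial_sigma_um: unusual for a light-sheet PSF")
  structure(list(lateral_sigma_um = lateral_sigma_um,
                 axial_sigma_um = axial_sigma_um,
                 haze_strength = haze_strength,
                 haze_kernel_sigma_um = haze_kernel_sigma_um,
                 confocal_rejection = confocal_rejection,
                 photon_gain = photon_gain,
                 read_sigma = read_sigma,
                 background_offset = background_offset),
            class = "degradation_params")
}

#' Preset degradation parameter sets
#'
#' `lsfm_economy_params()` models the economical conventional-LSFM
#' acquisition used as network input (low light dose: ~8 expected photons at
#' unit intensity, full scattering haze, visible read noise and background).
#' `lsfm_quality_params()` models the confocal line-scanning ground-truth
#' acquisition: the same optics but 3000x the photon budget and strong
#' (97%) rejection of scattered light.
#'
#' @return A `degradation_params` object.
#' @export
lsfm_economy_params <- function() {
  degradation_params(haze_strength = 1.0, confocal_rejection = 1.0,
                     photon_gain = 8, read_sigma = 0.03,
                     background_offset = 0.05)
}

#' @rdname lsfm_economy_params
#' @export
lsfm_quality_params <- function() {
  degradation_params(haze_strength = 1.0, confocal_rejection = 0.03,
                     photon_gain = 24000, read_sigma = 0.005,
                     background_offset = 0.005)
}

#' Apply the anisotropic PSF blur
#'
#' Separable Gaussian blur with lateral sigma in y/x and axial sigma in z,
#' converted from micrometres to voxels using the volume's voxel size.
#' Boundary handling is half-sample symmetric reflection, which keeps
#' constant signals invariant and conserves interior flux to within 1%.
#'
#' @param volume `volume3d` or 3D array.
#' @param params a [degradation_params()] object.
#' @return blurred volume, same shape/class.
#' @export
apply_psf <- function(volume, params) {
  stopifnot(inherits(params, "degradation_params"))
  vs <- voxel_size(volume)
  sig <- c(params$axial_sigma_um / vs[1],
           params$lateral_sigma_um / vs[2],
           params$lateral_sigma_um / vs[3])
  rewrap(gauss_blur3(vol_values(volume), sig), volume)
}

#' Add long-range scattering haze
#'
#' Returns `volume + confocal_rejection * haze_strength * (volume %*% K) +
#' background_offset`, where `K` is a wide normalized Gaussian kernel
#' (`haze_kernel_sigma_um`, default 10 um, i.e. far wider than the PSF).
#' The additive signal-correlated term reproduces how multiple scattering
#' redistributes ballistic photons into a smooth veil; line-confocal
#' detection suppresses it by the factor `confocal_rejection`. Haze is
#' depth-independent in this model (documented simplification).
#'
#' @inheritParams apply_psf
#' @return hazy volume, same shape/class.
#' @export
add_scatter_haze <- function(volume, params) {
  stopifnot(inherits(params, "degradation_params"))
  v <- vol_values(volume)
  amp <- params$confocal_rejection * params$haze_strength
  out <- if (amp > 0) {
    vs <- voxel_size(volume)
    sig <- params$haze_kernel_sigma_um / vs
    v + amp * gauss_blur3(v, sig) + params$background_offset
  } else {
    v + params$background_offset
  }
  rewrap(out, volume)
}

#' Add photon-limited Poisson-Gaussian noise
#'
#' Voxelwise `Poisson(gain * v) / gain + Normal(0, read_sigma)`, the standard
#' sCMOS shot + read noise model; `photon_gain` encodes the light dose, and
#' `photon_gain = Inf` is the noiseless (infinite-dose) limit where the shot
#' term is skipped. Deterministic given `seed`. Negative input intensities
#' are clamped to 0 before the Poisson draw (with a warning).
#'
#' @inheritParams apply_psf
#' @param seed integer RNG seed.
#' @return noisy volume, same shape/class.
#' @export
add_noise <- function(volume, params, seed) {
  stopifnot(inherits(params, "degradation_params"))
  v <- vol_values(volume)
  if (any(v < 0)) {
    warning("negative intensities clamped to 0 before Poisson draw")
    v <- pmax(v, 0)
  }
  n <- length(v)
  out <- with_seed(seed, {
    shot <- if (is.finite(params$photon_gain)) {
      rpois(n, lambda = params$photon_gain * as.vector(v)) / params$photon_gain
    } else as.vector(v)
    if (params$read_sigma > 0) shot <- shot + rnorm(n, 0, params$read_sigma)
    array(shot, dim(v))
  })
  rewrap(out, volume)
}

#' Simulate an aligned input / ground-truth training pair
#'
#' Applies the full forward model (PSF blur, then scattering haze, then
#' noise) twice to the same phantom: once with economical conventional-LSFM
#' parameters (the network input) and once with confocal high-dose
#' parameters (the ground truth). The pair is pixel-aligned by construction.
#'
#' @param phantom a `phantom3d` / `volume3d` / 3D array.
#' @param input_params,gt_params [degradation_params()] for the two arms. A
#'   warning is issued if the ground-truth arm is not cleaner (lower
#'   `confocal_rejection`, higher `photon_gain`) than the input arm.
#' @param seed integer; the two noise draws use seeds derived from it.
#' @param store_phantom keep the phantom inside the returned object (used by
#'   tests that need the noiseless reference).
#' @return A `paired_volume`: list with `input`, `ground_truth` (both
#'   `volume3d`), `input_params`, `gt_params`, `seed`.
#' @export
make_training_pair <- function(phantom,
                               input_params = lsfm_economy_params(),
                               gt_params = lsfm_quality_params(),
                               seed = 1, store_phantom = FALSE) {
  if (gt_params$confocal_rejection >= input_params$confocal_rejection ||
      gt_params$photon_gain <= input_params$photon_gain)
    warning(paste("ground-truth arm is not cleaner than the input arm",
                  "(expected lower confocal_rejection and higher photon_gain)"))
  blurred_in <- apply_psf(as_volume3d(phantom), input_params)
  same_psf <- isTRUE(all.equal(input_params[c("lateral_sigma_um", "axial_sigma_um")],
                               gt_params[c("lateral_sigma_um", "axial_sigma_um")]))
  blurred_gt <- if (same_psf) blurred_in else apply_psf(as_volume3d(phantom), gt_params)
  degrade <- function(blurred, params, s) {
    add_noise(add_scatter_haze(blurred, params), params, s)
  }
  out <- structure(list(
    input = degrade(blurred_in, input_params, child_seed(seed, 1L)),
    ground_truth = degrade(blurred_gt, gt_params, child_seed(seed, 2L)),
    input_params = input_params, gt_params = gt_params, seed = seed),
    class = "paired_volume")
  if (store_phantom) out$phantom <- phantom
  out
}

#' @export
print.paired_volume <- function(x, ...) {
  cat(sprintf("<paired_volume> %s voxels, seed %d\n",
              paste(dim(x$input), collapse = "x"), x$seed))
  invisible(x)
}

#' Simulate a dataset of training pairs
#'
#' Generates `n` phantoms with per-pair seeds derived from `seed` (varying
#' the chamber geometry slightly between pairs) and degrades each into an
#' aligned input / ground-truth pair.
#'
#' @param n number of pairs.
#' @param shape volume shape, each dim `>= 8`.
#' @inheritParams make_training_pair
#' @return list of `paired_volume`.
#' @export
simulate_training_pairs <- function(n, shape = c(32, 32, 32),
                                    input_params = lsfm_economy_params(),
                                    gt_params = lsfm_quality_params(),
                                    seed = 1, store_phantom = FALSE) {
  lapply(seq_len(n), function(i) {
    si <- child_seed(seed, 100L + i)
    jit <- with_seed(si, list(
      centers = rbind(c(0.18, 0.20, 0.12), c(-0.32, -0.26, -0.20)) +
        matrix(runif(6, -0.08, 0.08), 2, 3),
      radii = rbind(c(0.46, 0.42, 0.40), c(0.34, 0.30, 0.28)) *
        (1 + matrix(runif(6, -0.12, 0.12), 2, 3))
    ))
    ph <- generate_heart_phantom(shape, geometry = jit, seed = child_seed(si, 3L))
    make_training_pair(ph, input_params, gt_params, seed = child_seed(si, 4L),
                       store_phantom = store_phantom)
  })
}

#' Write a training pair to disk
#'
#' Writes the input and ground-truth volumes as two 32-bit float multi-page
#' TIFF stacks plus a JSON sidecar holding both degradation parameter sets
#' and the seed.
#'
#' @param pair a `paired_volume`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the three file paths.
#' @export
write_training_pair <- function(pair, dir, prefix = "pair") {
  stopifnot(inherits(pair, "paired_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_in <- file.path(dir, paste0(prefix, "_input.tif"))
  p_gt <- file.path(dir, paste0(prefix, "_gt.tif"))
  write_volume_tiff(pair$input, p_in)
  write_volume_tiff(pair$ground_truth, p_gt)
  p_js <- file.path(dir, paste0(prefix, "_params.json"))
  jsonlite::write_json(list(input_params = unclass(pair$input_params),
                            gt_params = unclass(pair$gt_params),
                            seed = pair$seed),
                       p_js, auto_unbox = TRUE, digits = NA)
  invisible(c(input = p_in, ground_truth = p_gt, params = p_js))
}

#' Read back a training pair written to disk
#'
#' Counterpart of [write_training_pair()]: reconstructs a `paired_volume`
#' from the two TIFF stacks and the JSON sidecar.
#'
#' @param dir directory containing the pair files.
#' @param prefix file-name prefix used at write time.
#' @return a `paired_volume`.
#' @export
read_training_pair <- function(dir, prefix = "pair") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_params.json")),
                              simplifyVector = TRUE)
  mk <- function(p) do.call(degradation_params, as.list(p))
  structure(list(
    input = read_volume_tiff(file.path(dir, paste0(prefix, "_input.tif"))),
    ground_truth = read_volume_tiff(file.path(dir, paste0(prefix, "_gt.tif"))),
    input_params = mk(meta$input_params), gt_params = mk(meta$gt_params),
    seed = meta$seed), class = "paired_volume")
}
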