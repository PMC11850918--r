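#' Normalized root-mean-square error
#'
#' RMSE between test and reference, divided by the reference intensity
#' range (max - min). Small values indicate better agreement; 0 iff the
#' volumes are identical.
#'
#' @param test,reference volumes of identical shape; the reference must not
#'   be constant.
#' @return non-negative scalar.
#' @export
compute_nrmse <- function(test, reference) {
  a <- vol_values(test); b <- vol_values(reference)
  check_same_shape(a, b)
  rng <- max(b) - min(b)
  if (rng <= 0) stop("constant reference volume: NRMSE undefined", call. = FALSE)
  sqrt(mean((a - b)^2)) / rng
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: (%s) vs (%s)", paste(dim(a), collapse = ","),
                 paste(dim(b), collapse = ",")), call. = FALSE)
}

#' Pearson correlation between volumes
#'
#' Standard product-moment correlation over all voxels.
#'
#' @param a,b volumes of identical shape, both non-constant.
#' @return scalar in `[-1, 1]`.
#' @export
compute_pearson <- function(a, b) {
  av <- vol_values(a); bv <- vol_values(b)
  check_same_shape(av, bv)
  if (var(as.vector(av)) == 0 || var(as.vector(bv)) == 0)
    stop("zero-variance input: Pearson correlation undefined", call. = FALSE)
  cor(as.vector(av), as.vector(bv))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(data_range^2 / MSE)`. For identical volumes (MSE = 0) the
#' documented ceiling of 120 dB is returned with attribute `capped = TRUE`.
#'
#' @param test,reference volumes of identical shape.
#' @param data_range intensity range of the data (default 1, the package's
#'   post-normalization convention).
#' @return scalar in dB.
#' @export
compute_psnr <- function(test, reference, data_range = 1) {
  a <- vol_values(test); b <- vol_values(reference)
  check_same_shape(a, b)
  stopifnot_scalar_num(data_range, "data_range", min = 1e-12)
  mse <- mean((a - b)^2)
  if (mse == 0) return(structure(120, capped = TRUE))
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (slice-averaged)
#'
#' Standard SSIM computed per z-slice with a Gaussian window (sigma = 1.5,
#' 11 x 11, reflect boundary), constants `K1 = 0.01`, `K2 = 0.03`,
#' population covariance, a border strip of the window radius excluded, and
#' the mean taken over slices. These conventions follow the classic Wang et
#' al. formulation, so single-slice values agree with reference 2D
#' implementations.
#'
#' @param test,reference volumes (or single 2D slices) of identical shape;
#'   slice dims must be at least the 11-voxel window.
#' @param data_range intensity range (default 1).
#' @param K1,K2 stability constants.
#' @param sigma Gaussian window sd in voxels.
#' @return scalar in `[-1, 1]`; 1 iff identical.
#' @export
compute_ssim <- function(test, reference, data_range = 1, K1 = 0.01,
                         K2 = 0.03, sigma = 1.5) {
  a <- vol_values(test); b <- vol_values(reference)
  if (length(dim(a)) == 2L) { dim(a) <- c(1L, dim(a)); dim(b) <- c(1L, dim(b)) }
  check_same_shape(a, b)
  d <- dim(a)
  r <- as.integer(3.5 * sigma + 0.5)
  win <- 2L * r + 1L
  if (d[2] < win || d[3] < win)
    stop(sprintf("slices must be at least %d x %d for SSIM", win, win),
         call. = FALSE)
  GH <- gauss1d_matrix(d[2], sigma)
  GW <- gauss1d_matrix(d[3], sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  keep_h <- (r + 1L):(d[2] - r); keep_w <- (r + 1L):(d[3] - r)
  f <- function(m) GH %*% m %*% t(GW)
  mean(vapply(seq_len(d[1]), function(z) {
    x <- a[z, , ]; y <- b[z, , ]
    ux <- f(x); uy <- f(y)
    vx <- f(x * x) - ux * ux
    vy <- f(y * y) - uy * uy
    vxy <- f(x * y) - ux * uy
    S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
      ((ux^2 + uy^2 + C1) * (vx + vy + C2))
    mean(S[keep_h, keep_w])
  }, 0))
}

#' Foreground/background masks by Otsu thresholding
#'
#' Computes the Otsu threshold of a volume (256-bin histogram) and returns
#' disjoint foreground (`> threshold`) and background masks. Conventionally
#' computed on the ground-truth volume so that input, restored and GT
#' volumes are scored over identical regions.
#'
#' @param volume `volume3d` or 3D array.
#' @param levels histogram bins.
#' @return list with logical arrays `fg`, `bg` and the `threshold`.
#' @export
otsu_masks <- function(volume, levels = 256L) {
  v <- as.vector(vol_values(volume))
  rng <- range(v)
  if (diff(rng) <= 0) stop("constant volume: Otsu threshold undefined",
                           call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  thr <- mids[which.max(between)]
  vv <- vol_values(volume)
  list(fg = vv > thr, bg = vv <= thr, threshold = thr)
}

#' Signal-to-noise ratio with explicit masks (dB)
#'
#' `10 * log10((mu_fg - mu_bg)^2 / sigma_bg^2)`: the squared
#' foreground/background mean separation over the background variance.
#' When the separation is zero the documented floor of -120 dB is returned
#' with attribute `floored = TRUE`.
#'
#' @param volume `volume3d` or 3D array.
#' @param fg_mask,bg_mask disjoint non-empty logical masks; the background
#'   must be non-constant.
#' @return scalar in dB.
#' @export
compute_snr_db <- function(volume, fg_mask, bg_mask) {
  v <- vol_values(volume)
  fg_mask <- as.logical(fg_mask); bg_mask <- as.logical(bg_mask)
  if (!any(fg_mask) || !any(bg_mask)) stop("empty mask", call. = FALSE)
  if (any(fg_mask & bg_mask)) stop("masks must be disjoint", call. = FALSE)
  mu_fg <- mean(v[fg_mask]); mu_bg <- mean(v[bg_mask])
  s_bg <- sd(v[bg_mask])
  if (s_bg == 0) stop("constant background: SNR undefined", call. = FALSE)
  num <- (mu_fg - mu_bg)^2
  if (num == 0) return(structure(-120, floored = TRUE))
  10 * log10(num / s_bg^2)
}

michelson_contrast <- function(v, fg_mask, bg_mask) {
  mu_fg <- mean(v[fg_mask]); mu_bg <- mean(v[bg_mask])
  den <- mu_fg + mu_bg
  if (den <= 0) stop("non-positive contrast denominator (mu_fg + mu_bg <= 0)",
                     call. = FALSE)
  (mu_fg - mu_bg) / den
}

#' Contrast enhancement relative to the input acquisition
#'
#' Michelson-style contrast `C = (mu_fg - mu_bg) / (mu_fg + mu_bg)`
#' computed over the same masks on a processed volume and on the raw input,
#' returned as the ratio `C_test / C_input`. Removing a uniform additive
#' haze offset raises `C`, so values `> 1` indicate haze/background
#' suppression.
#'
#' @param test processed volume.
#' @param reference_input the unprocessed input volume.
#' @param fg_mask,bg_mask masks as in [compute_snr_db()].
#' @return positive scalar; 1 when `test == reference_input`.
#' @export
compute_contrast_enhancement <- function(test, reference_input, fg_mask,
                                         bg_mask) {
  a <- vol_values(test); b <- vol_values(reference_input)
  check_same_shape(a, b)
  fg_mask <- as.logical(fg_mask); bg_mask <- as.logical(bg_mask)
  if (!any(fg_mask) || !any(bg_mask)) stop("empty mask", call. = FALSE)
  michelson_contrast(a, fg_mask, bg_mask) /
    michelson_contrast(b, fg_mask, bg_mask)
}

#' Full metric report for an (input, restored, GT) triplet
#'
#' Computes the six evaluation metrics. Reference-based metrics (NRMSE,
#' Pearson, PSNR, SSIM) compare against the ground truth and ignore masks;
#' SNR, contrast and contrast enhancement use foreground/background masks
#' derived from the ground-truth volume by Otsu thresholding (or supplied
#' masks).
#'
#' @param input,restored,gt volumes of identical shape.
#' @param masks optional list with `fg`, `bg`; default Otsu masks of `gt`.
#' @param data_range intensity range for PSNR/SSIM.
#' @return a `metric_report` data frame: one row per volume
#'   (input/restored) with columns `nrmse`, `pearson`, `psnr_db`, `ssim`,
#'   `snr_db`, `contrast`, `contrast_enhancement`, plus attribute
#'   `masks_provenance`.
#' @export
metric_report <- function(input, restored, gt, masks = NULL, data_range = 1) {
  vi <- vol_values(input); vr <- vol_values(restored); vg <- vol_values(gt)
  check_same_shape(vi, vg); check_same_shape(vr, vg)
  prov <- if (is.null(masks)) "otsu(gt)" else "user"
  if (is.null(masks)) masks <- otsu_masks(vg)
  row <- function(v, name) {
    data.frame(volume = name,
               nrmse = compute_nrmse(v, vg),
               pearson = compute_pearson(v, vg),
               psnr_db = as.numeric(compute_psnr(v, vg, data_range)),
               ssim = compute_ssim(v, vg, data_range),
               snr_db = as.numeric(compute_snr_db(v, masks$fg, masks$bg)),
               contrast = michelson_contrast(v, masks$fg, masks$bg),
               contrast_enhancement =
                 compute_contrast_enhancement(v, vi, masks$fg, masks$bg))
  }
  out <- rbind(row(vi, "input"), row(vr, "restored"))
  gtrow <- data.frame(volume = "gt", nrmse = 0, pearson = 1,
                      psnr_db = as.numeric(compute_psnr(vg, vg, data_range)),
                      ssim = 1,
                      snr_db = as.numeric(compute_snr_db(vg, masks$fg, masks$bg)),
                      contrast = michelson_contrast(vg, masks$fg, masks$bg),
                      contrast_enhancement =
                        compute_contrast_enhancement(vg, vi, masks$fg, masks$bg))
  out <- rbind(out, gtrow)
  structure(out, masks_provenance = prov, class = c("metric_report",
                                                    class(out)))
}

#' Acquisition specification
#'
#' Illumination power, per-plane exposure and plane count of an
#' acquisition, the quantities entering light-dose and acquisition-time
#' arithmetic.
#'
#' @param illumination_power_mw laser power at the sample (mW).
#' @param exposure_per_plane_ms camera exposure per plane (ms).
#' @param planes number of planes in the volume.
#' @return an `acquisition_spec`.
#' @export
acquisition_spec <- function(illumination_power_mw, exposure_per_plane_ms,
                             planes = 1L) {
  stopifnot_scalar_num(illumination_power_mw, "illumination_power_mw", min = 1e-12)
  stopifnot_scalar_num(exposure_per_plane_ms, "exposure_per_plane_ms", min = 1e-12)
  stopifnot_scalar_num(planes, "planes", min = 1)
  structure(list(illumination_power_mw = illumination_power_mw,
                 exposure_per_plane_ms = exposure_per_plane_ms,
                 planes = as.integer(planes)),
            class = "acquisition_spec")
}

#' Acquisition-economy ratios
#'
#' Light-dose ratio (power x exposure x planes) and acquisition-time ratio
#' (exposure x planes) of acquisition `a` relative to acquisition `b`. The
#' confocal ground-truth protocol (10 mW, 300 ms/plane) versus the
#' economical training input (0.1 mW, 10 ms/plane) gives 3000x the dose and
#' 30x the time; an in vivo time-lapse plane (0.1 mW, 3 ms) uses 1e-4 of
#' the ground-truth dose (0.01% light exposure) and 1% of its time.
#'
#' @param a,b [acquisition_spec()] objects.
#' @return named list `dose_ratio`, `time_ratio`.
#' @export
economy_ratios <- function(a, b) {
  stopifnot(inherits(a, "acquisition_spec"), inherits(b, "acquisition_spec"))
  dose <- function(s) s$illumination_power_mw * s$exposure_per_plane_ms * s$planes
  tt <- function(s) s$exposure_per_plane_ms * s$planes
  list(dose_ratio = dose(a) / dose(b), time_ratio = tt(a) / tt(b))
}
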