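#' Generate a two-chamber heart-like phantom
#'
#' Builds a fluorophore-density phantom emulating an embryonic heart: two
#' overlapping ellipsoidal shells (an "atrium" and a "ventricle") whose thin
#' walls mimic the slender myocardial layer, modulated by a seeded
#' cell-scale multiplicative speckle texture so that detail preservation can
#' be probed. Densities are in `[0, 1]`; the output is a deterministic
#' function of `(shape, geometry, seed)`.
#'
#' @param shape integer 3-vector `(D, H, W)`, each `>= 8`.
#' @param geometry list overriding any of: `centers` (2 x 3 matrix, chamber
#'   centers in normalized `[-1,1]` coordinates), `radii` (2 x 3 matrix,
#'   normalized semi-axes), `wall_thickness` (relative shell width, `>= 0`,
#'   default 0.14), `wall_intensity` (peak density, default 0.9),
#'   `background` (uniform base level, default 0.02), `texture_strength`
#'   (speckle contrast, default 0.35), `texture_scale_vox` (speckle
#'   correlation length in voxels, default 1.5).
#' @param seed integer RNG seed for the texture.
#' @param voxel_size_um voxel pitch passed to [volume3d()].
#' @return A `phantom3d` object (a [volume3d()] with generation metadata).
#' @export
generate_heart_phantom <- function(shape = c(64, 64, 64), geometry = list(),
                                   seed = 1, voxel_size_um = c(0.325, 0.325, 0.325)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 8L))
    stop("`shape` must be 3 integers, each >= 8", call. = FALSE)
  g <- modifyList(list(
    centers = rbind(c(0.18, 0.20, 0.12), c(-0.32, -0.26, -0.20)),
    radii = rbind(c(0.46, 0.42, 0.40), c(0.34, 0.30, 0.28)),
    wall_thickness = 0.14,
    wall_intensity = 0.9,
    background = 0.02,
    texture_strength = 0.35,
    texture_scale_vox = 1.5
  ), geometry)
  if (g$wall_thickness < 0) stop("`wall_thickness` must be >= 0", call. = FALSE)

  ax <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  Z <- array(ax[[1]], shape)
  Y <- aperm(array(ax[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
  X <- aperm(array(ax[[3]], shape[c(3, 1, 2)]), c(2, 3, 1))

  shell <- array(0, shape)
  if (g$wall_thickness > 0) {
    for (ch in 1:2) {
      f <- sqrt(((Z - g$centers[ch, 1]) / g$radii[ch, 1])^2 +
                ((Y - g$centers[ch, 2]) / g$radii[ch, 2])^2 +
                ((X - g$centers[ch, 3]) / g$radii[ch, 3])^2)
      shell <- pmax(shell, exp(-0.5 * ((f - 1) / (g$wall_thickness / 2))^2))
    }
  }

  tex <- with_seed(seed, {
    noise <- array(rnorm(prod(shape)), shape)
    sm <- gauss_blur3(noise, rep(g$texture_scale_vox, 3L))
    sm <- sm / max(sd(sm), 1e-12)
    pmax(1 + g$texture_strength * sm, 0)
  })

  values <- pmin(pmax(g$background + g$wall_intensity * shell * tex, 0), 1)
  out <- volume3d(values, voxel_size_um)
  attr(out, "phantom") <- list(shape = shape, geometry = g, seed = seed)
  class(out) <- c("phantom3d", class(out))
  out
}

#' Periodic beating deformation of a phantom
#'
#' Produces a 4D sequence by smooth periodic radial dilation/contraction of
#' the phantom about the volume center, the synthetic analogue of a heartbeat
#' cycle. Frame `t` depends only on `(t - 1 + phase0) mod period_frames`, so
#' noiseless sequences are exactly periodic.
#'
#' @param phantom a `phantom3d`/`volume3d`/3D array.
#' @param n_frames total number of frames, `>= period_frames`.
#' @param period_frames cycle length in frames, `>= 2`.
#' @param phase0 integer starting phase in `[0, period_frames)`.
#' @param amplitude peak relative radial dilation (e.g. 0.08 = 8%). Values
#'   pulling samples outside the volume are clamped with a warning.
#' @return A `beating_phantom4d`: list with `frames` (list of 3D arrays),
#'   `period_frames`, `phase0`, `voxel_size_um`.
#' @export
deform_beating <- function(phantom, n_frames, period_frames, phase0 = 0,
                           amplitude = 0.08) {
  n_frames <- as.integer(n_frames); period_frames <- as.integer(period_frames)
  phase0 <- as.integer(phase0)
  if (period_frames < 2L) stop("`period_frames` must be >= 2", call. = FALSE)
  if (n_frames < period_frames) stop("`n_frames` must be >= `period_frames`", call. = FALSE)
  if (phase0 < 0L || phase0 >= period_frames)
    stop("`phase0` must be in [0, period_frames)", call. = FALSE)
  v <- vol_values(phantom)
  d <- dim(v)
  ctr <- (d + 1) / 2
  base <- array(seq_len(prod(d)), d)  # linear index grid for coordinates
  zi <- ((base - 1) %% d[1]) + 1
  yi <- (((base - 1) %/% d[1]) %% d[2]) + 1
  xi <- ((base - 1) %/% (d[1] * d[2])) + 1

  phases <- unique((seq_len(n_frames) - 1L + phase0) %% period_frames)
  frame_for_phase <- vector("list", period_frames)
  clamped_any <- FALSE
  for (ph in phases) {
    s <- 1 + amplitude * sin(2 * pi * ph / period_frames)
    if (s == 1) {
      frame_for_phase[[ph + 1L]] <- v
    } else {
      sm <- trilinear_sample(v, ctr[1] + (zi - ctr[1]) / s,
                             ctr[2] + (yi - ctr[2]) / s,
                             ctr[3] + (xi - ctr[3]) / s)
      clamped_any <- clamped_any || sm$clamped
      frame_for_phase[[ph + 1L]] <- array(sm$values, d)
    }
  }
  if (clamped_any)
    warning("deformation sampled outside the volume; coordinates were clamped")
  frames <- lapply(seq_len(n_frames) - 1L, function(t)
    frame_for_phase[[((t + phase0) %% period_frames) + 1L]])
  structure(list(frames = frames, period_frames = period_frames,
                 phase0 = phase0, voxel_size_um = voxel_size(phantom)),
            class = "beating_phantom4d")
}

#' @export
print.beating_phantom4d <- function(x, ...) {
  cat(sprintf("<beating_phantom4d> %d frames of %s voxels, period %d, phase0 %d\n",
              length(x$frames), paste(dim(x$frames[[1]]), collapse = "x"),
              x$period_frames, x$phase0))
  invisible(x)
}
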