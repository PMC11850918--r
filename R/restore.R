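#' Tiled inference with overlap blending
#'
#' Restores arbitrarily sized volumes through a model whose forward pass
#' requires dimensions divisible by a power of two: the volume is covered
#' by overlapping tiles, each tile is restored directly, and tiles are
#' mosaicked with a separable cosine (Hann-ramp) weight window normalized
#' to a partition of unity. Volumes smaller than one tile are
#' reflect-padded, restored in one pass, and cropped back.
#'
#' @param model a `uitrans_model` (or a `uitrans` fit, whose model is
#'   used).
#' @param volume input volume.
#' @param tile 3-vector tile size; each dim must be divisible by the
#'   architecture's required multiple.
#' @param overlap overlap between adjacent tiles in voxels (`>= 0`, less
#'   than half the smallest tile dim).
#' @return restored volume, same shape as the input.
#' @export
tiled_restore <- function(model, volume, tile = c(64L, 64L, 64L),
                          overlap = 8L) {
  if (inherits(model, "uitrans")) model <- model$model
  stopifnot(inherits(model, "uitrans_model"))
  tile <- as.integer(rep(tile, length.out = 3L))
  overlap <- as.integer(overlap)
  req <- required_multiple(model$config)
  if (any(tile %% req != 0L))
    stop(sprintf("tile dims must be divisible by %d", req), call. = FALSE)
  if (overlap < 0L || overlap >= min(tile) / 2)
    stop("`overlap` must be >= 0 and < tile/2", call. = FALSE)
  x <- vol_values(volume)
  d <- dim(x)

  # reflect-pad any axis smaller than the tile
  pad_lo <- pmax((tile - d) %/% 2L, 0L)
  pad_hi <- pmax(tile - d - pad_lo, 0L)
  if (any(pad_lo > 0L | pad_hi > 0L)) x <- reflect_pad(x, pad_lo, pad_hi)
  dp <- dim(x)

  step <- pmax(tile - overlap, 1L)
  corners <- lapply(1:3, function(a) {
    if (dp[a] <= tile[a]) return(1L)
    cs <- seq(1L, dp[a] - tile[a] + 1L, by = step[a])
    unique(c(cs, dp[a] - tile[a] + 1L))
  })
  w1 <- lapply(1:3, function(a) tile_window(tile[a], overlap))
  acc <- array(0, dp); wacc <- array(0, dp)
  for (cz in corners[[1]]) for (cy in corners[[2]]) for (cx in corners[[3]]) {
    iz <- cz:(cz + tile[1] - 1L); iy <- cy:(cy + tile[2] - 1L)
    ix <- cx:(cx + tile[3] - 1L)
    yt <- uitrans_fw(model, x[iz, iy, ix, drop = FALSE], cache = FALSE,
                     apply_final = FALSE)
    w <- outer(outer(w1[[1]], w1[[2]]), w1[[3]])
    dim(w) <- tile
    acc[iz, iy, ix] <- acc[iz, iy, ix] + yt * w
    wacc[iz, iy, ix] <- wacc[iz, iy, ix] + w
  }
  out <- acc / wacc
  out <- out[(pad_lo[1] + 1L):(pad_lo[1] + d[1]),
             (pad_lo[2] + 1L):(pad_lo[2] + d[2]),
             (pad_lo[3] + 1L):(pad_lo[3] + d[3]), drop = FALSE]
  if (model$config$final_activation == "clamp01") out <- pmin(pmax(out, 0), 1)
  rewrap(out, volume)
}

# cosine ramp of width `overlap` at both ends of a length-n window
tile_window <- function(n, overlap) {
  w <- rep(1, n)
  if (overlap > 0L) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(overlap) - 0.5) / overlap)
    w[seq_len(overlap)] <- ramp
    w[(n - overlap + 1L):n] <- rev(ramp)
  }
  w
}

reflect_pad <- function(x, lo, hi) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    j <- c(if (lo[a] > 0L) (1L - lo[a]):0L, seq_len(d[a]),
           if (hi[a] > 0L) d[a] + seq_len(hi[a]))
    reflect_index(j, d[a])
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
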