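#' Single-channel 3D intensity volume
#'
#' A `volume3d` is a plain numeric 3D array (depth `D` x height `H` x width
#' `W`, i.e. z-slices along the first dimension) carrying a voxel-size
#' attribute in micrometres. All simulator, model and metric functions accept
#' either a `volume3d` or a bare 3D array.
#'
#' @param values numeric 3D array `(D, H, W)`, all finite.
#' @param voxel_size_um positive length-3 numeric `(z, y, x)` voxel pitch in
#'   micrometres. The default 0.325 um matches a 20x/sCMOS light-sheet
#'   detection path.
#' @return A `volume3d` object.
#' @export
volume3d <- function(values, voxel_size_um = c(0.325, 0.325, 0.325)) {
  values <- unclass(values)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (!all(is.finite(values))) stop("volume values must be finite", call. = FALSE)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 3 positive numbers", call. = FALSE)
  structure(values, voxel_size_um = as.numeric(voxel_size_um),
            class = c("volume3d", "array"))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size_um")
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x), %.3g x %.3g x %.3g um/voxel\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @rdname volume3d
#' @param x object to convert.
#' @export
as_volume3d <- function(x, voxel_size_um = NULL) {
  if (inherits(x, "volume3d")) {
    if (!is.null(voxel_size_um)) attr(x, "voxel_size_um") <- voxel_size_um
    return(x)
  }
  volume3d(x, voxel_size_um %||% c(0.325, 0.325, 0.325))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vol_values <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

voxel_size <- function(x) attr(x, "voxel_size_um") %||% c(0.325, 0.325, 0.325)

#' Read and write volumes as multi-page TIFF
#'
#' Volumes are stored as 32-bit float multi-page TIFF with plane order = z
#' (first array dimension). Intensities are clipped to `[0, 1]` on write, the
#' convention used throughout the package after normalization. An optional
#' JSON sidecar (same path with extension `.json`) records voxel size and any
#' extra metadata.
#'
#' @param vol a `volume3d` or 3D array.
#' @param path output TIFF file path.
#' @param metadata named list stored in the JSON sidecar (written when
#'   non-NULL).
#' @return `write_volume_tiff` returns `path` invisibly; `read_volume_tiff`
#'   returns a `volume3d`.
#' @export
write_volume_tiff <- function(vol, path, metadata = NULL) {
  v <- pmin(pmax(vol_values(vol), 0), 1)
  slices <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(voxel_size_um = voxel_size(vol), shape = dim(v)),
            metadata)
  if (!is.null(metadata) || TRUE) {
    jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- dim(slices[[1]])
  v <- array(0, c(length(slices), d[1], d[2]))
  for (z in seq_along(slices)) v[z, , ] <- slices[[z]]
  vs <- c(0.325, 0.325, 0.325)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um)) vs <- as.numeric(meta$voxel_size_um)
  }
  volume3d(v, vs)
}

#' Percentile-normalize a volume to [0, 1]
#'
#' Affine map sending the `lo_pct` / `hi_pct` intensity percentiles to 0 / 1,
#' then clipping. Robust percentile scaling (rather than min/max) keeps a few
#' hot voxels or haze offsets from compressing the dynamic range.
#'
#' @param volume `volume3d` or 3D array.
#' @param lo_pct,hi_pct percentiles in `[0, 100]`, `lo_pct < hi_pct`.
#' @return normalized volume of the same class/shape.
#' @export
normalize_volume <- function(volume, lo_pct = 0.1, hi_pct = 99.9) {
  stopifnot_scalar_num(lo_pct, "lo_pct", 0, 100)
  stopifnot_scalar_num(hi_pct, "hi_pct", 0, 100)
  if (lo_pct >= hi_pct) stop("`lo_pct` must be < `hi_pct`", call. = FALSE)
  v <- vol_values(volume)
  q <- quantile(v, c(lo_pct, hi_pct) / 100, names = FALSE)
  if (q[2] - q[1] <= 0) {
    warning("constant volume: returning all-0.5 output")
    out <- array(0.5, dim(v))
  } else {
    out <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  rewrap(out, volume)
}

rewrap <- function(values, template) {
  if (inherits(template, "volume3d")) volume3d(values, voxel_size(template))
  else values
}

#' Crop a volume to an exact size
#'
#' @param volume `volume3d` or 3D array.
#' @param size target `(D, H, W)`, each `<=` the volume shape.
#' @param anchor `"center"` (default) or `"corner"` (origin voxel).
#' @return cropped volume.
#' @export
crop_to_size <- function(volume, size, anchor = c("center", "corner")) {
  anchor <- match.arg(anchor)
  v <- vol_values(volume)
  d <- dim(v)
  size <- as.integer(size)
  if (length(size) != 3L || any(size < 1L)) stop("`size` must be 3 positive ints")
  if (any(size > d))
    stop(sprintf("crop size (%s) exceeds volume shape (%s)",
                 paste(size, collapse = ","), paste(d, collapse = ",")),
         call. = FALSE)
  start <- if (anchor == "center") (d - size) %/% 2L + 1L else rep(1L, 3L)
  out <- v[start[1]:(start[1] + size[1] - 1L),
           start[2]:(start[2] + size[2] - 1L),
           start[3]:(start[3] + size[3] - 1L), drop = FALSE]
  rewrap(out, volume)
}

# Integer translation with constant padding. `shift` moves content toward
# higher indices: out[i] = x[i - shift].
translate_volume <- function(x, shift, pad = 0) {
  d <- dim(x)
  out <- array(pad, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s) }
    else { dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}
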