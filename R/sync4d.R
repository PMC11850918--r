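#' Per-slice time-series movies of a beating volume
#'
#' Reslices a periodic 4D phantom into the acquisition geometry of
#' heartbeat imaging: for each z-slice a movie of `T` consecutive frames,
#' each slice starting at its own (unknown to the reconstruction) cardiac
#' phase, as happens when planes are acquired sequentially. Optional
#' Gaussian noise emulates the low-dose time-lapse regime.
#'
#' @param beating a `beating_phantom4d` covering at least one full period
#'   (only the first period is used; the cycle is exactly periodic).
#' @param T_frames frames per slice movie (`>= 2 * period`).
#' @param offsets integer per-slice start phases in `[0, period)`; default
#'   random, drawn from `seed`.
#' @param noise_sd additive Gaussian noise sd (0 = noiseless).
#' @param frame_interval_ms frame spacing metadata.
#' @param seed RNG seed for offsets and noise.
#' @return A `slice_movie_set`: list with `movies` (list over z of
#'   `(T, H, W)` arrays), `frame_interval_ms`, `T_frames`,
#'   `period_frames`, and `true_offsets` (kept for validation studies).
#' @export
make_slice_movies <- function(beating, T_frames, offsets = NULL,
                              noise_sd = 0, frame_interval_ms = 3,
                              seed = 1) {
  stopifnot(inherits(beating, "beating_phantom4d"))
  p <- beating$period_frames
  if (T_frames < 2L * p) stop("`T_frames` must cover at least 2 periods",
                              call. = FALSE)
  d <- dim(beating$frames[[1]])
  nz <- d[1]
  cycle <- beating$frames[seq_len(p)]  # frames 1..p are phases phase0..; use phase0=0
  if (beating$phase0 != 0L)
    cycle <- beating$frames[((seq_len(p) - 1L - beating$phase0) %% p) + 1L]
  if (is.null(offsets)) {
    offsets <- with_seed(seed, sample.int(p, nz, replace = TRUE) - 1L)
  }
  offsets <- as.integer(offsets) %% p
  if (length(offsets) != nz) stop("`offsets` must have one entry per slice")
  movies <- vector("list", nz)
  for (z in seq_len(nz)) {
    mv <- array(0, c(T_frames, d[2], d[3]))
    for (t in seq_len(T_frames)) {
      ph <- (t - 1L + offsets[z]) %% p
      mv[t, , ] <- cycle[[ph + 1L]][z, , ]
    }
    if (noise_sd > 0) {
      mv <- mv + with_seed(child_seed(seed, 500L + z),
                           array(rnorm(length(mv), 0, noise_sd), dim(mv)))
    }
    movies[[z]] <- mv
  }
  structure(list(movies = movies, frame_interval_ms = frame_interval_ms,
                 T_frames = as.integer(T_frames), period_frames = p,
                 true_offsets = offsets),
            class = "slice_movie_set")
}

#' @export
print.slice_movie_set <- function(x, ...) {
  d <- dim(x$movies[[1]])
  cat(sprintf("<slice_movie_set> %d slices x %d frames of %dx%d px (%g ms/frame)\n",
              length(x$movies), d[1], d[2], d[3], x$frame_interval_ms))
  invisible(x)
}

movie_trace <- function(movie, roi_quantile = 0.9) {
  d <- dim(movie)
  px <- matrix(movie, nrow = d[1])
  v <- apply(px, 2, var)
  thr <- quantile(v, roi_quantile, names = FALSE)
  roi <- v >= thr
  if (!any(roi)) roi <- rep(TRUE, length(v))
  rowMeans(px[, roi, drop = FALSE])
}

#' Estimate the cardiac period from a single-slice movie
#'
#' Autocorrelation of the mean-intensity trace within an auto-selected
#' high-variance region of interest; the period is the lag of the dominant
#' autocorrelation peak (excluding lag 0), refined to sub-frame precision
#' by parabolic interpolation and reported rounded.
#'
#' @param movie `(T, H, W)` frame stack (or a bare numeric trace), `T >= 3`
#'   and non-constant.
#' @param min_peak minimum autocorrelation a peak must reach to count as
#'   periodic (default 0.2).
#' @return integer period in frames, with attribute `refined` (the
#'   sub-frame estimate) and `peak` (autocorrelation at the peak).
#' @export
estimate_period <- function(movie, min_peak = 0.2) {
  trace <- if (is.null(dim(movie))) as.numeric(movie) else movie_trace(movie)
  T_frames <- length(trace)
  if (T_frames < 3L) stop("need at least 3 frames", call. = FALSE)
  if (sd(trace) == 0) stop("aperiodic signal: movie trace is constant",
                           call. = FALSE)
  lag_max <- floor(T_frames / 2)
  ac <- as.numeric(acf(trace, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)
  # local maxima over lags 1..lag_max (ac[k+1] is lag k)
  peaks <- which(diff(sign(diff(ac))) == -2)  # indices into ac, lag = idx - 1
  peaks <- peaks[peaks > 1L]
  if (!length(peaks) || max(ac[peaks]) < min_peak)
    stop("aperiodic signal: no dominant autocorrelation peak", call. = FALSE)
  k <- peaks[which.max(ac[peaks])]
  lag <- k - 1L
  refined <- lag
  if (k > 1L && k < length(ac)) {
    y0 <- ac[k - 1L]; y1 <- ac[k]; y2 <- ac[k + 1L]
    den <- y0 - 2 * y1 + y2
    if (den < 0) refined <- lag + 0.5 * (y0 - y2) / den
  }
  structure(as.integer(round(refined)), refined = refined, peak = ac[k])
}

circular_lag_cor <- function(a, b, p) {
  T_frames <- length(a)
  n <- T_frames - p
  sapply(0:(p - 1L), function(l) {
    suppressWarnings(cor(a[1:n], b[(1 + l):(n + l)]))
  })
}

#' Synchronize per-slice movies into a 4D reconstruction
#'
#' Post-acquisition cardiac-cycle synchronization: each slice's phase
#' offset is chained pairwise by maximizing the circular cross-correlation
#' between the high-variance-ROI intensity traces of adjacent slices; a 3D
#' volume is then assembled for each of the `period_frames` phase bins by
#' nearest-frame selection. Offsets are defined modulo the period and up to
#' a global constant (the phase origin), so reconstructions are unique up
#' to a cyclic rotation of the phase axis.
#'
#' @param movies a `slice_movie_set` (or list of `(T, H, W)` arrays).
#' @param period_frames cardiac period in frames; `NULL` to estimate from
#'   the first slice and validate (within +/- 1 frame) on the others.
#' @param cor_threshold adjacent-slice correlation below which the previous
#'   offset is propagated with a warning (default 0.3).
#' @param validate_period check per-slice period estimates (default TRUE
#'   when `period_frames` is NULL).
#' @return A `heartbeat4d`: list with `volumes` (list of `period_frames`
#'   3D arrays), `period_frames`, `offsets` (estimated per-slice phase
#'   offsets).
#' @export
synchronize_movies <- function(movies, period_frames = NULL,
                               cor_threshold = 0.3,
                               validate_period = is.null(period_frames)) {
  mv <- if (inherits(movies, "slice_movie_set")) movies$movies else movies
  nz <- length(mv)
  d <- dim(mv[[1]])
  T_frames <- d[1]
  traces <- lapply(mv, movie_trace)
  if (is.null(period_frames)) {
    ref_z <- which.max(vapply(traces, sd, 0))
    period_frames <- as.integer(estimate_period(mv[[ref_z]]))
  }
  p <- as.integer(period_frames)
  if (T_frames < 2L * p)
    stop("movies must cover at least 2 periods", call. = FALSE)
  if (validate_period) {
    check_z <- unique(round(seq(1, nz, length.out = min(nz, 5L))))
    for (z in check_z) {
      pz <- try(as.integer(estimate_period(mv[[z]])), silent = TRUE)
      if (!inherits(pz, "try-error") && abs(pz - p) > 1L)
        warning(sprintf("slice %d period estimate (%d) deviates from %d", z, pz, p))
    }
  }
  # Chain per-slice offsets against the previous `chain_depth` slices,
  # weighting each anchor by its trace amplitude. Multi-anchor evidence
  # protects the chain from single weak or phase-ambiguous links (e.g.
  # slices at a chamber pole, where the mean-intensity trace inverts).
  chain_depth <- 3L
  offsets <- integer(nz)
  sds <- vapply(traces, sd, 0)
  for (z in 2:nz) {
    anchors <- max(1L, z - chain_depth):(z - 1L)
    score <- numeric(p)
    for (k in anchors) {
      cc <- circular_lag_cor(traces[[z]], traces[[k]], p)
      cc[is.na(cc)] <- 0
      for (o in 0:(p - 1L)) {
        l <- (o - offsets[k]) %% p
        score[o + 1L] <- score[o + 1L] + sds[k] * cc[l + 1L]
      }
    }
    quality <- max(score) / max(sum(sds[anchors]), 1e-12)
    if (quality < cor_threshold) {
      warning(sprintf(
        "slice %d: adjacent-slice correlation below %.2f; propagating offset",
        z, cor_threshold))
      offsets[z] <- offsets[z - 1L]
    } else offsets[z] <- which.max(score) - 1L
  }
  volumes <- vector("list", p)
  for (ph in 0:(p - 1L)) {
    vol <- array(0, c(nz, d[2], d[3]))
    for (z in seq_len(nz)) {
      t <- ((ph - offsets[z]) %% p) + 1L
      vol[z, , ] <- mv[[z]][t, , ]
    }
    volumes[[ph + 1L]] <- vol
  }
  structure(list(volumes = volumes, period_frames = p, offsets = offsets),
            class = "heartbeat4d")
}

#' @export
print.heartbeat4d <- function(x, ...) {
  cat(sprintf("<heartbeat4d> %d phase bins of %s voxels\n", x$period_frames,
              paste(dim(x$volumes[[1]]), collapse = "x")))
  invisible(x)
}

#' Write a 4D reconstruction to disk
#'
#' One multi-page TIFF per phase bin plus an index JSON recording the
#' period and per-slice offsets.
#'
#' @param hb a `heartbeat4d`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_heartbeat4d <- function(hb, dir, prefix = "phase") {
  stopifnot(inherits(hb, "heartbeat4d"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(hb$period_frames)
  for (i in seq_len(hb$period_frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.tif", prefix, i - 1L))
    write_volume_tiff(hb$volumes[[i]], paths[i])
  }
  idx <- file.path(dir, paste0(prefix, "_index.json"))
  jsonlite::write_json(list(period_frames = hb$period_frames,
                            offsets = hb$offsets, files = basename(paths)),
                       idx, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, idx))
}
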