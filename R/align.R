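#' Rigid translational registration by Pearson correlation
#'
#' Exhaustive search over integer-voxel translations in all three axes
#' (jointly, up to `max_shift` per axis), maximizing the Pearson
#' correlation computed over the overlap region only (no zero-fill bias).
#' Ties are broken by the smallest shift magnitude, then lexicographically.
#' For `max_shift > 8` a coarse-to-fine strategy (x2 mean-pooled prescan,
#' then local +/-2 refinement at full resolution) keeps the search cheap.
#' Sub-voxel interpolation is deliberately not performed: the goal is
#' pixel-level alignment of input/ground-truth acquisitions.
#'
#' @param moving,reference volumes of identical shape, both non-constant.
#' @param max_shift maximum |shift| per axis in voxels, `>= 0`.
#' @param axis_wise search each axis independently (sequentially) instead
#'   of jointly; default `FALSE` (joint 3D search).
#' @return list with `shift` (integer `(dz, dy, dx)`: the estimated
#'   displacement of `moving` relative to `reference`), `pearson_at_best`,
#'   and `aligned` (the moving volume translated by `-shift` into the
#'   reference frame, padded with the background estimate, the median of
#'   the moving volume's faces).
#' @export
rigid_align <- function(moving, reference, max_shift = 4L, axis_wise = FALSE) {
  mv <- vol_values(moving); rf <- vol_values(reference)
  check_same_shape(mv, rf)
  max_shift <- as.integer(max_shift)
  if (max_shift < 0L) stop("`max_shift` must be >= 0", call. = FALSE)
  if (var(as.vector(mv)) == 0 || var(as.vector(rf)) == 0)
    stop("no signal: constant volume cannot be registered", call. = FALSE)
  best <- if (axis_wise) {
    sh <- c(0L, 0L, 0L)
    for (a in 1:3) {
      cand <- lapply(-max_shift:max_shift, function(s) {
        x <- sh; x[a] <- s; x
      })
      sh <- search_shifts(mv, rf, cand)$shift
    }
    search_shifts(mv, rf, list(sh))
  } else if (max_shift > 8L) {
    mv2 <- pool2(mv); rf2 <- pool2(rf)
    coarse <- search_shifts(mv2, rf2, grid_shifts(ceiling(max_shift / 2L)))$shift
    center <- 2L * coarse
    cand <- lapply(grid_shifts(2L), function(s) {
      pmin(pmax(center + s, -max_shift), max_shift)
    })
    search_shifts(mv, rf, unique(cand))
  } else {
    search_shifts(mv, rf, grid_shifts(max_shift))
  }
  bg <- median(c(mv[1, , ], mv[dim(mv)[1], , ], mv[, 1, ], mv[, dim(mv)[2], ],
                 mv[, , 1], mv[, , dim(mv)[3]]))
  aligned <- translate_volume(mv, -best$shift, pad = bg)
  list(shift = best$shift, pearson_at_best = best$pearson,
       aligned = rewrap(aligned, moving))
}

grid_shifts <- function(m) {
  g <- expand.grid(dz = -m:m, dy = -m:m, dx = -m:m)
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

pool2 <- function(x) {
  d <- dim(x) %/% 2L * 2L
  x <- x[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  0.125 * (x[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
           x[seq(2, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
           x[seq(1, d[1], 2), seq(2, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
           x[seq(1, d[1], 2), seq(1, d[2], 2), seq(2, d[3], 2), drop = FALSE] +
           x[seq(2, d[1], 2), seq(2, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
           x[seq(2, d[1], 2), seq(1, d[2], 2), seq(2, d[3], 2), drop = FALSE] +
           x[seq(1, d[1], 2), seq(2, d[2], 2), seq(2, d[3], 2), drop = FALSE] +
           x[seq(2, d[1], 2), seq(2, d[2], 2), seq(2, d[3], 2), drop = FALSE])
}

# Pearson correlation over the overlap under the hypothesis that `moving`
# is the reference displaced by `s` (moving[i] == reference[i - s]).
shift_pearson <- function(mv, rf, s) {
  d <- dim(mv)
  if (any(abs(s) >= d)) return(NA_real_)
  ridx <- midx <- vector("list", 3L)
  for (a in 1:3) {
    if (s[a] >= 0) { midx[[a]] <- (1 + s[a]):d[a]; ridx[[a]] <- 1:(d[a] - s[a]) }
    else { midx[[a]] <- 1:(d[a] + s[a]); ridx[[a]] <- (1 - s[a]):d[a] }
  }
  a <- mv[midx[[1]], midx[[2]], midx[[3]]]
  b <- rf[ridx[[1]], ridx[[2]], ridx[[3]]]
  if (var(as.vector(a)) == 0 || var(as.vector(b)) == 0) return(NA_real_)
  cor(as.vector(a), as.vector(b))
}

search_shifts <- function(mv, rf, shifts) {
  # order by magnitude then lexicographic so ties resolve to the smallest
  ord <- order(vapply(shifts, function(s) sum(s^2), 0),
               vapply(shifts, function(s) s[1], 0),
               vapply(shifts, function(s) s[2], 0),
               vapply(shifts, function(s) s[3], 0))
  best_p <- -Inf; best_s <- shifts[[ord[1]]]
  for (i in ord) {
    p <- shift_pearson(mv, rf, shifts[[i]])
    if (!is.na(p) && p > best_p + 1e-12) { best_p <- p; best_s <- shifts[[i]] }
  }
  list(shift = as.integer(best_s), pearson = best_p)
}
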