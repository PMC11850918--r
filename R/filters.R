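# Separable filtering via mode products: a 1D operator applied along one axis
# of a 3D/4D array is a dense matrix multiply on the matricized array. Volumes
# here are small enough (<= 256 per axis) that dense operator matrices are
# both exact and fast (BLAS).

# Half-sample symmetric reflection of 1-based index j into [1, n].
reflect_index <- function(j, n) {
  j <- (j - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# n x n matrix applying a normalized Gaussian (sd `sigma` in voxels) along an
# axis of length n with reflect boundary handling. Rows sum to 1, so constant
# signals are invariant and interior flux is conserved.
gauss1d_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  w <- dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- reflect_index(i + (-r:r), n)
    for (t in seq_along(idx)) M[i, idx[t]] <- M[i, idx[t]] + w[t]
  }
  M
}

# Apply matrix M (m x d[axis]) along `axis` of array x (3D or 4D).
axis_mult <- function(x, M, axis) {
  d <- dim(x)
  k <- length(d)
  perm <- c(axis, setdiff(seq_len(k), axis))
  xm <- matrix(aperm(x, perm), nrow = d[axis])
  ym <- M %*% xm
  dout <- d
  dout[axis] <- nrow(M)
  y <- array(ym, dout[perm])
  aperm(y, order(perm))
}

# Separable Gaussian blur of a 3D array, sigma per axis in voxels.
gauss_blur3 <- function(x, sigma_vox) {
  d <- dim(x)
  for (a in 1:3) {
    if (sigma_vox[a] > 0) x <- axis_mult(x, gauss1d_matrix(d[a], sigma_vox[a]), a)
  }
  x
}

# Trilinear sampling of 3D array `x` at fractional coordinates (1-based).
# Coordinates are clamped to the volume; returns list(values, clamped).
trilinear_sample <- function(x, cz, cy, cx) {
  d <- dim(x)
  clamped <- any(cz < 1 | cz > d[1] | cy < 1 | cy > d[2] | cx < 1 | cx > d[3])
  cz <- pmin(pmax(cz, 1), d[1]); cy <- pmin(pmax(cy, 1), d[2])
  cx <- pmin(pmax(cx, 1), d[3])
  z0 <- pmin(floor(cz), d[1] - 1L); y0 <- pmin(floor(cy), d[2] - 1L)
  x0 <- pmin(floor(cx), d[3] - 1L)
  fz <- cz - z0; fy <- cy - y0; fx <- cx - x0
  idx <- function(z, y, xx) z + d[1] * (y - 1) + d[1] * d[2] * (xx - 1)
  v <- x[idx(z0, y0, x0)] * (1 - fz) * (1 - fy) * (1 - fx) +
    x[idx(z0 + 1, y0, x0)] * fz * (1 - fy) * (1 - fx) +
    x[idx(z0, y0 + 1, x0)] * (1 - fz) * fy * (1 - fx) +
    x[idx(z0, y0, x0 + 1)] * (1 - fz) * (1 - fy) * fx +
    x[idx(z0 + 1, y0 + 1, x0)] * fz * fy * (1 - fx) +
    x[idx(z0 + 1, y0, x0 + 1)] * fz * (1 - fy) * fx +
    x[idx(z0, y0 + 1, x0 + 1)] * (1 - fz) * fy * fx +
    x[idx(z0 + 1, y0 + 1, x0 + 1)] * fz * fy * fx
  list(values = v, clamped = clamped)
}
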