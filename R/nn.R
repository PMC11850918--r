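# Minimal dense-layer toolkit used by the restoration network. Feature maps
# are channel-last 4D arrays (D, H, W, C); token matrices are (N_tokens x E).
# Every forward returns what its matching backward needs; all heavy lifting
# (im2col convolution, token gather/scatter) is in compiled code.

to4d <- function(x) {
  x <- vol_values(x)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

channels4 <- function(x) dim(x)[4]

conv_fw <- function(x, W, b, k = c(3L, 3L, 3L), s = c(1L, 1L, 1L),
                    p = (k - 1L) %/% 2L) {
  .conv3d_fw_cpp(x, dim(x), W, b, as.integer(k), as.integer(s), as.integer(p))
}

conv_bw <- function(x, W, dy, k = c(3L, 3L, 3L), s = c(1L, 1L, 1L),
                    p = (k - 1L) %/% 2L, need_dx = TRUE) {
  .conv3d_bw_cpp(x, dim(x), W, dy, as.integer(k), as.integer(s), as.integer(p),
                 need_dx)
}

lrelu <- function(x, slope = 0.1) {
  neg <- x < 0
  x - (1 - slope) * (x * neg)
}
dlrelu <- function(x, slope = 0.1) 1 - (1 - slope) * (x < 0)

gelu <- function(x) x * pnorm(x)
dgelu <- function(x) pnorm(x) + x * dnorm(x)

addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

layernorm_fw <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = addb(sweep(xhat, 2, g, "*"), b), xhat = xhat, inv = inv)
}

layernorm_bw <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Multi-head self-attention on a token matrix X (N x E). Heads partition the
# embedding; per-token attention rows are softmax-normalized.
mha_fw <- function(X, pm, heads) {
  E <- ncol(X); dh <- E %/% heads
  Q <- addb(X %*% pm$Wq, pm$bq)
  K <- addb(X %*% pm$Wk, pm$bk)
  V <- addb(X %*% pm$Wv, pm$bv)
  A <- vector("list", heads)
  O <- matrix(0, nrow(X), E)
  for (h in seq_len(heads)) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    A[[h]] <- softmax_rows(Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) /
                             sqrt(dh))
    O[, ix] <- A[[h]] %*% V[, ix, drop = FALSE]
  }
  Y <- addb(O %*% pm$Wo, pm$bo)
  list(y = Y, Q = Q, K = K, V = V, A = A, O = O, X = X, heads = heads, dh = dh)
}

mha_bw <- function(dy, cache, pm) {
  heads <- cache$heads; dh <- cache$dh
  dWo <- t(cache$O) %*% dy
  dbo <- colSums(dy)
  dO <- dy %*% t(pm$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(dy), ncol(dy))
  for (h in seq_len(heads)) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    Vh <- cache$V[, ix, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, ix] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE] / sqrt(dh)
    dK[, ix] <- t(dS) %*% cache$Q[, ix, drop = FALSE] / sqrt(dh)
  }
  dX <- dQ %*% t(pm$Wq) + dK %*% t(pm$Wk) + dV %*% t(pm$Wv)
  list(dx = dX,
       g = list(Wq = t(cache$X) %*% dQ, bq = colSums(dQ),
                Wk = t(cache$X) %*% dK, bk = colSums(dK),
                Wv = t(cache$X) %*% dV, bv = colSums(dV),
                Wo = dWo, bo = dbo))
}

# --- trilinear x2 upsampling as dense per-axis operators --------------------
.up_cache <- new.env(parent = emptyenv())

upsample_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.up_cache[[key]])) return(.up_cache[[key]])
  U <- matrix(0, 2L * n, n)
  for (j in 0:(2L * n - 1L)) {
    cc <- j / 2 - 0.25
    i0 <- floor(cc); f <- cc - i0
    for (pair in list(c(i0, 1 - f), c(i0 + 1, f))) {
      i <- min(max(pair[1], 0), n - 1)
      U[j + 1L, i + 1L] <- U[j + 1L, i + 1L] + pair[2]
    }
  }
  .up_cache[[key]] <- U
  U
}

up2_fw <- function(x) {
  d <- dim(x)
  for (a in 1:3) x <- axis_mult(x, upsample_matrix(d[a]), a)
  x
}

up2_bw <- function(dy, in_dims) {
  for (a in 1:3) dy <- axis_mult(dy, t(upsample_matrix(in_dims[a])), a)
  dy
}

# --- initializers (draw from the current RNG stream) ------------------------
init_conv_w <- function(k, c_in, c_out) {
  fan_in <- prod(k) * c_in
  bound <- sqrt(6 / fan_in)
  list(W = matrix(runif(fan_in * c_out, -bound, bound), fan_in, c_out),
       b = rep(0, c_out))
}

trunc_normal <- function(n, sd = 0.02) pmin(pmax(rnorm(n, 0, sd), -2 * sd), 2 * sd)

init_lin_w <- function(n_in, n_out, sd = 0.02) {
  list(W = matrix(trunc_normal(n_in * n_out, sd), n_in, n_out),
       b = rep(0, n_out))
}

# --- parameter-tree utilities -----------------------------------------------
tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_leaves <- function(tree) {
  if (is.list(tree)) unlist(lapply(tree, tree_leaves), recursive = FALSE,
                            use.names = FALSE)
  else list(tree)
}

tree_size <- function(tree) sum(vapply(tree_leaves(tree), length, 0L))

zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

# One ADAM update; `state` holds (m, v, t). Returns list(params, state).
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

adam_init <- function(params) list(m = zeros_like(params), v = zeros_like(params),
                                   t = 0L)
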