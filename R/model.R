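#' Network architecture configuration
#'
#' Hyperparameters of the dual-branch U-type restoration network. The
#' encoder has `n_stages` stages; at stage `i` the convolutional branch (a
#' double 3x3x3 convolution block) and the transformer branch (a block of
#' two parallel multi-headed self-attention modules whose outputs are
#' channel-concatenated) each emit `base_channels * 2^i` channels, are
#' down-sampled x2 by strided convolution, and are concatenated along
#' channels; the concatenated map is both the skip connection and the next
#' stage's input. The decoder mirrors the convolutional branch with
#' trilinear x2 up-sampling plus double convolutions and a final 1x1x1
#' projection.
#'
#' Tokenization for attention uses interval extraction: the volume is split
#' into non-overlapping `s^3` cells of strided sub-samples, one token per
#' cell, so tokens cover the field of view globally rather than locally.
#' `token_stride` sets the stride at the deepest stage; shallower stages
#' double it, which keeps the token-sequence length constant across stages
#' and bounds attention cost at full resolution.
#'
#' @param n_stages number of encoder stages (default 3).
#' @param base_channels channel width multiplier (default 16).
#' @param n_heads attention heads (default 4).
#' @param mlp_ratio hidden width of the token MLP relative to the embedding
#'   (default 2).
#' @param token_stride interval-extraction stride at the deepest stage
#'   (default 2).
#' @param transformer_branch,conv_branch branch toggles for ablation; at
#'   least one must be enabled.
#' @param final_activation `"none"` (default) or `"clamp01"` (clamp applied
#'   at inference only).
#' @param embed_mult attention embedding width as a multiple of the per-MSA
#'   output channels (default 4).
#' @param pos_embedding add a learned positional embedding to the token
#'   sequence (default `FALSE`; when `TRUE` the model is tied to the
#'   build-time token-grid size).
#' @return A `uitrans_config` object.
#' @export
uitrans_config <- function(n_stages = 3L, base_channels = 16L, n_heads = 4L,
                           mlp_ratio = 2, token_stride = 2L,
                           transformer_branch = TRUE, conv_branch = TRUE,
                           final_activation = c("none", "clamp01"),
                           embed_mult = 4L, pos_embedding = FALSE) {
  final_activation <- match.arg(final_activation)
  n_stages <- as.integer(n_stages); base_channels <- as.integer(base_channels)
  n_heads <- as.integer(n_heads); token_stride <- as.integer(token_stride)
  if (n_stages < 1L) stop("`n_stages` must be >= 1", call. = FALSE)
  if (base_channels < 1L) stop("`base_channels` must be >= 1", call. = FALSE)
  if (token_stride < 1L) stop("`token_stride` must be >= 1", call. = FALSE)
  if (!transformer_branch && !conv_branch)
    stop("invalid config: at least one of the two encoder branches must be enabled",
         call. = FALSE)
  if (transformer_branch && (embed_mult * base_channels) %% n_heads != 0L)
    stop("embedding width (embed_mult * base_channels) must be divisible by n_heads",
         call. = FALSE)
  structure(list(n_stages = n_stages, base_channels = base_channels,
                 n_heads = n_heads, mlp_ratio = mlp_ratio,
                 token_stride = token_stride,
                 transformer_branch = isTRUE(transformer_branch),
                 conv_branch = isTRUE(conv_branch),
                 final_activation = final_activation,
                 embed_mult = as.integer(embed_mult),
                 pos_embedding = isTRUE(pos_embedding)),
            class = "uitrans_config")
}

#' @rdname uitrans_config
#' @details `uitrans_config_desk()` is the documented desk-scale preset
#'   (`base_channels = 8`, otherwise defaults) used throughout the package's
#'   examples and training property checks: small enough that a full
#'   simulate-train-evaluate cycle on 32^3 volumes runs in minutes on one
#'   CPU core while keeping the full dual-branch topology.
#' @export
uitrans_config_desk <- function(...) uitrans_config(base_channels = 8L, ...)

# Channel/stride bookkeeping, one row per encoder stage:
#   c_in   input channels of both branches
#   c_out  channels each branch emits (base * 2^i)
#   c_msa  channels per MSA module (c_out / 2, twin concat restores c_out)
#   stride interval-extraction stride (token_stride * 2^(n - i))
#   embed  attention embedding width (embed_mult * c_msa)
#   width  channels of the stage output / skip (sum over enabled branches)
uitrans_schedule <- function(config) {
  n <- config$n_stages
  branches <- config$conv_branch + config$transformer_branch
  c_in <- 1L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    c_out <- config$base_channels * 2L^i
    c_msa <- c_out %/% 2L
    rows[[i]] <- data.frame(stage = i, c_in = c_in, c_out = c_out,
                            c_msa = c_msa,
                            stride = config$token_stride * 2L^(n - i),
                            embed = config$embed_mult * c_msa,
                            width = branches * c_out)
    c_in <- rows[[i]]$width
  }
  do.call(rbind, rows)
}

# Required divisor of every spatial input dim: 2^n for the down/up path and
# stride * 2^(i-1) for each stage's tokenization (all powers of two).
required_multiple <- function(config) {
  n <- config$n_stages
  req <- 2^n
  if (config$transformer_branch)
    req <- max(req, config$token_stride * 2^(n - 1L))
  as.integer(req)
}

msa_init <- function(c_in, c_out, s, E, mlp_ratio, n_tokens = NULL,
                     pos_embedding = FALSE) {
  H <- as.integer(round(mlp_ratio * E))
  pm <- list(We = init_lin_w(s^3 * c_in, E)$W, be = rep(0, E),
             ln1g = rep(1, E), ln1b = rep(0, E),
             Wq = init_lin_w(E, E)$W, bq = rep(0, E),
             Wk = init_lin_w(E, E)$W, bk = rep(0, E),
             Wv = init_lin_w(E, E)$W, bv = rep(0, E),
             Wo = init_lin_w(E, E)$W, bo = rep(0, E),
             ln2g = rep(1, E), ln2b = rep(0, E),
             W1 = init_lin_w(E, H)$W, b1 = rep(0, H),
             W2 = init_lin_w(H, E)$W, b2 = rep(0, E),
             Wp = init_lin_w(E, s^3 * c_out)$W, bp = rep(0, s^3 * c_out))
  if (pos_embedding) {
    if (is.null(n_tokens))
      stop("pos_embedding requires a declared input shape at build time")
    pm$pos <- matrix(trunc_normal(n_tokens * E), n_tokens, E)
  }
  pm
}

msa_forward <- function(x, pm, s, heads, c_out) {
  d <- dim(x)
  od <- d[1:3] %/% s
  tok <- .token_gather_cpp(x, d, as.integer(s))
  z0 <- addb(tok %*% pm$We, pm$be)
  if (!is.null(pm$pos)) {
    if (nrow(pm$pos) != nrow(z0))
      stop(sprintf("positional embedding built for %d tokens, input has %d",
                   nrow(pm$pos), nrow(z0)), call. = FALSE)
    z0 <- z0 + pm$pos
  }
  l1 <- layernorm_fw(z0, pm$ln1g, pm$ln1b)
  att <- mha_fw(l1$y, pm, heads)
  z1 <- z0 + att$y
  l2 <- layernorm_fw(z1, pm$ln2g, pm$ln2b)
  h1 <- addb(l2$y %*% pm$W1, pm$b1)
  a1 <- gelu(h1)
  m <- addb(a1 %*% pm$W2, pm$b2)
  z2 <- z1 + m
  ot <- addb(z2 %*% pm$Wp, pm$bp)
  y <- .token_scatter_cpp(ot, as.integer(od), as.integer(s), as.integer(c_out))
  list(y = y, cache = list(tok = tok, z0 = z0, l1 = l1, att = att, z1 = z1,
                           l2 = l2, h1 = h1, a1 = a1, z2 = z2, d = d, od = od))
}

msa_backward <- function(dy, cache, pm, s, heads, c_in, c_out, need_dx = TRUE) {
  dot <- .token_gather_cpp(dy, dim(dy), as.integer(s))
  g <- list()
  g$Wp <- t(cache$z2) %*% dot; g$bp <- colSums(dot)
  dz2 <- dot %*% t(pm$Wp)
  # MLP sub-block (residual: z2 = z1 + MLP(LN2(z1)))
  dm <- dz2
  g$W2 <- t(cache$a1) %*% dm; g$b2 <- colSums(dm)
  da1 <- dm %*% t(pm$W2)
  dh1 <- da1 * dgelu(cache$h1)
  g$W1 <- t(cache$l2$y) %*% dh1; g$b1 <- colSums(dh1)
  dl2 <- dh1 %*% t(pm$W1)
  ln2 <- layernorm_bw(dl2, cache$l2, pm$ln2g)
  g$ln2g <- ln2$dg; g$ln2b <- ln2$db
  dz1 <- dz2 + ln2$dx
  # attention sub-block (residual: z1 = z0 + MHA(LN1(z0)))
  att <- mha_bw(dz1, cache$att, pm)
  g <- c(g, att$g)
  ln1 <- layernorm_bw(att$dx, cache$l1, pm$ln1g)
  g$ln1g <- ln1$dg; g$ln1b <- ln1$db
  dz0 <- dz1 + ln1$dx
  if (!is.null(pm$pos)) g$pos <- dz0
  g$We <- t(cache$tok) %*% dz0; g$be <- colSums(dz0)
  dx <- NULL
  if (need_dx) {
    dtok <- dz0 %*% t(pm$We)
    dx <- .token_scatter_cpp(dtok, as.integer(cache$od), as.integer(s),
                             as.integer(c_in))
  }
  # reorder to the parameter layout so tree operations line up
  ord <- c("We", "be", "ln1g", "ln1b", "Wq", "bq", "Wk", "bk", "Wv", "bv",
           "Wo", "bo", "ln2g", "ln2b", "W1", "b1", "W2", "b2", "Wp", "bp")
  if (!is.null(pm$pos)) ord <- c(ord, "pos")
  list(dx = dx, g = g[ord])
}

dconv_init <- function(c_in, c_mid, c_out) {
  list(c1 = init_conv_w(c(3, 3, 3), c_in, c_mid),
       c2 = init_conv_w(c(3, 3, 3), c_mid, c_out))
}

dconv_fw <- function(x, pc) {
  y1 <- conv_fw(x, pc$c1$W, pc$c1$b)
  a1 <- lrelu(y1)
  y2 <- conv_fw(a1, pc$c2$W, pc$c2$b)
  list(y = lrelu(y2), cache = list(x = x, y1 = y1, a1 = a1, y2 = y2))
}

dconv_bw <- function(dy, cache, pc, need_dx = TRUE) {
  d2 <- dy * dlrelu(cache$y2)
  b2 <- conv_bw(cache$a1, pc$c2$W, d2)
  d1 <- b2$dx * dlrelu(cache$y1)
  b1 <- conv_bw(cache$x, pc$c1$W, d1, need_dx = need_dx)
  list(dx = b1$dx,
       g = list(c1 = list(W = b1$dW, b = b1$db), c2 = list(W = b2$dW, b = b2$db)))
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

split_c <- function(x, c1) {
  list(x[, , , seq_len(c1), drop = FALSE],
       x[, , , (c1 + 1L):dim(x)[4], drop = FALSE])
}

#' Build an untrained restoration network
#'
#' Allocates and seed-initializes all parameters for the configured
#' architecture. Convolution weights use Kaiming-uniform initialization;
#' attention/MLP weights use a truncated normal (sd 0.02).
#'
#' @param config a [uitrans_config()].
#' @param seed integer initialization seed; identical `(config, seed)` give
#'   bit-identical parameters.
#' @param input_shape required only when `pos_embedding = TRUE` (the learned
#'   embedding is sized to the token grid of this shape).
#' @return A `uitrans_model`: list with `params`, `config`, `seed`,
#'   `schedule` (the channel bookkeeping table) and `n_params`.
#' @export
build_uitrans <- function(config = uitrans_config(), seed = 1,
                          input_shape = NULL) {
  stopifnot(inherits(config, "uitrans_config"))
  sched <- uitrans_schedule(config)
  n <- config$n_stages
  params <- with_seed(seed, {
    P <- list(enc = vector("list", n), dec = list(), head = NULL)
    for (i in seq_len(n)) {
      row <- sched[i, ]
      st <- list()
      if (config$conv_branch) {
        st$cv <- dconv_init(row$c_in, row$c_out, row$c_out)
        st$cv$dn <- init_conv_w(c(2, 2, 2), row$c_out, row$c_out)
      }
      if (config$transformer_branch) {
        n_tok <- NULL
        if (config$pos_embedding) {
          if (is.null(input_shape))
            stop("pos_embedding = TRUE requires `input_shape` at build time")
          res <- as.integer(input_shape) %/% 2L^(i - 1L)
          n_tok <- prod(res %/% row$stride)
        }
        st$tr <- list(
          m1 = msa_init(row$c_in, row$c_msa, row$stride, row$embed,
                        config$mlp_ratio, n_tok, config$pos_embedding),
          m2 = msa_init(row$c_in, row$c_msa, row$stride, row$embed,
                        config$mlp_ratio, n_tok, config$pos_embedding),
          dn = init_conv_w(c(2, 2, 2), row$c_out, row$c_out))
      }
      P$enc[[i]] <- st
    }
    widths <- sched$width
    x_ch <- widths[n]
    if (n > 1L) {
      P$dec <- vector("list", n - 1L)
      for (j in seq_len(n - 1L)) {
        i <- n - j
        lvl <- list(up = init_conv_w(c(3, 3, 3), x_ch, sched$c_out[i]))
        lvl <- c(lvl, dconv_init(sched$c_out[i] + widths[i], sched$c_out[i],
                                 sched$c_out[i]))
        P$dec[[j]] <- lvl
        x_ch <- sched$c_out[i]
      }
    }
    P$head <- list(up = init_conv_w(c(3, 3, 3), x_ch, config$base_channels),
                   c1 = init_conv_w(c(3, 3, 3), config$base_channels,
                                    config$base_channels),
                   out = init_conv_w(c(1, 1, 1), config$base_channels, 1L))
    P
  })
  model <- structure(list(params = params, config = config, seed = seed,
                          schedule = sched, input_shape = input_shape),
                     class = "uitrans_model")
  model$n_params <- count_parameters(model)
  model
}

#' @rdname build_uitrans
#' @param model a `uitrans_model`.
#' @export
count_parameters <- function(model) tree_size(model$params)

#' @export
print.uitrans_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<uitrans_model> %d stages, base %d, heads %d, token stride %d, %s\n",
    cfg$n_stages, cfg$base_channels, cfg$n_heads, cfg$token_stride,
    paste(c(if (cfg$conv_branch) "conv", if (cfg$transformer_branch) "transformer"),
          collapse = "+")))
  cat(sprintf("  %s parameters (seed %s)\n", format(x$n_params, big.mark = ","),
              format(x$seed)))
  invisible(x)
}

check_input_shape <- function(model, d) {
  req <- required_multiple(model$config)
  if (any(d %% req != 0L))
    stop(sprintf(
      "input shape (%s) invalid: each spatial dim must be divisible by %d",
      paste(d, collapse = ","), req), call. = FALSE)
}

# Full forward pass. With cache = TRUE returns list(y, cache) for backprop;
# otherwise returns just the output array (D, H, W).
uitrans_fw <- function(model, volume, cache = FALSE, apply_final = !cache) {
  x <- to4d(volume)
  if (!all(is.finite(x))) stop("non-finite values in input volume", call. = FALSE)
  check_input_shape(model, dim(x)[1:3])
  cfg <- model$config; P <- model$params; sched <- model$schedule
  n <- cfg$n_stages
  CC <- if (cache) list(enc = vector("list", n), dec = list()) else NULL
  skips <- vector("list", n)
  for (i in seq_len(n)) {
    row <- sched[i, ]
    st <- P$enc[[i]]
    sc <- list()
    parts <- list()
    if (cfg$conv_branch) {
      dc <- dconv_fw(x, st$cv)
      cvd <- conv_fw(dc$y, st$cv$dn$W, st$cv$dn$b, k = c(2, 2, 2), s = c(2, 2, 2),
                     p = c(0, 0, 0))
      parts <- c(parts, list(cvd))
      if (cache) sc$cv <- list(dc = dc$cache, y = dc$y)
    }
    if (cfg$transformer_branch) {
      m1 <- msa_forward(x, st$tr$m1, row$stride, cfg$n_heads, row$c_msa)
      m2 <- msa_forward(x, st$tr$m2, row$stride, cfg$n_heads, row$c_msa)
      tcat <- concat_c(m1$y, m2$y)
      td <- conv_fw(tcat, st$tr$dn$W, st$tr$dn$b, k = c(2, 2, 2), s = c(2, 2, 2),
                    p = c(0, 0, 0))
      parts <- c(parts, list(td))
      if (cache) sc$tr <- list(m1 = m1$cache, m2 = m2$cache, tcat = tcat)
    }
    skip <- if (length(parts) == 2L) concat_c(parts[[1]], parts[[2]]) else parts[[1]]
    skips[[i]] <- skip
    if (cache) { sc$x <- x; CC$enc[[i]] <- sc }
    x <- skip
  }
  if (n > 1L) {
    if (cache) CC$dec <- vector("list", n - 1L)
    for (j in seq_len(n - 1L)) {
      i <- n - j
      lvl <- P$dec[[j]]
      xin_dims <- dim(x)[1:3]
      xu <- up2_fw(x)
      yu <- conv_fw(xu, lvl$up$W, lvl$up$b)
      au <- lrelu(yu)
      xc <- concat_c(au, skips[[i]])
      dc <- dconv_fw(xc, lvl)
      if (cache) CC$dec[[j]] <- list(in_dims = xin_dims, xu = xu, yu = yu,
                                     au = au, xc = xc, dc = dc$cache,
                                     c_up = dim(au)[4])
      x <- dc$y
    }
  }
  hin_dims <- dim(x)[1:3]
  xu <- up2_fw(x)
  yu <- conv_fw(xu, P$head$up$W, P$head$up$b)
  au <- lrelu(yu)
  y1 <- conv_fw(au, P$head$c1$W, P$head$c1$b)
  a1 <- lrelu(y1)
  y <- conv_fw(a1, P$head$out$W, P$head$out$b, k = c(1, 1, 1), p = c(0, 0, 0))
  out <- array(y, dim(y)[1:3])
  if (apply_final && cfg$final_activation == "clamp01")
    out <- pmin(pmax(out, 0), 1)
  if (!cache) return(out)
  CC$head <- list(in_dims = hin_dims, xu = xu, yu = yu, au = au, y1 = y1, a1 = a1)
  CC$skip_dims <- lapply(skips, dim)
  list(y = out, cache = CC)
}

# Backward pass: gradient of a scalar loss wrt all parameters given dL/dy.
uitrans_bw <- function(model, cache, dy) {
  cfg <- model$config; P <- model$params; sched <- model$schedule
  n <- cfg$n_stages
  G <- list(enc = vector("list", n), dec = list(), head = NULL)
  hd <- cache$head
  dy4 <- array(dy, c(dim(dy), 1L))
  bo <- conv_bw(hd$a1, P$head$out$W, dy4, k = c(1, 1, 1), p = c(0, 0, 0))
  d1 <- bo$dx * dlrelu(hd$y1)
  b1 <- conv_bw(hd$au, P$head$c1$W, d1)
  du <- b1$dx * dlrelu(hd$yu)
  bu <- conv_bw(hd$xu, P$head$up$W, du)
  dx <- up2_bw(bu$dx, hd$in_dims)
  G$head <- list(up = list(W = bu$dW, b = bu$db),
                 c1 = list(W = b1$dW, b = b1$db),
                 out = list(W = bo$dW, b = bo$db))
  dskips <- vector("list", n)
  if (n > 1L) {
    G$dec <- vector("list", n - 1L)
    for (j in rev(seq_len(n - 1L))) {
      i <- n - j
      lvl <- P$dec[[j]]; dcch <- cache$dec[[j]]
      db <- dconv_bw(dx, dcch$dc, lvl)
      sp <- split_c(db$dx, dcch$c_up)
      dau <- sp[[1]]
      dskips[[i]] <- add_or_set(dskips[[i]], sp[[2]])
      dyu <- dau * dlrelu(dcch$yu)
      bu <- conv_bw(dcch$xu, lvl$up$W, dyu)
      dx <- up2_bw(bu$dx, dcch$in_dims)
      G$dec[[j]] <- list(up = list(W = bu$dW, b = bu$db), c1 = db$g$c1,
                         c2 = db$g$c2)
    }
  }
  dskips[[n]] <- add_or_set(dskips[[n]], dx)
  for (i in rev(seq_len(n))) {
    row <- sched[i, ]
    st <- P$enc[[i]]; sc <- cache$enc[[i]]
    dskip <- dskips[[i]]
    gi <- list()
    dxin <- NULL
    need_dx <- i > 1L
    if (cfg$conv_branch && cfg$transformer_branch) {
      sp <- split_c(dskip, row$c_out)
      dcv <- sp[[1]]; dtd <- sp[[2]]
    } else if (cfg$conv_branch) { dcv <- dskip; dtd <- NULL
    } else { dcv <- NULL; dtd <- dskip }
    if (cfg$conv_branch) {
      bdn <- conv_bw(sc$cv$y, st$cv$dn$W, dcv, k = c(2, 2, 2), s = c(2, 2, 2),
                     p = c(0, 0, 0))
      bdc <- dconv_bw(bdn$dx, sc$cv$dc, st$cv, need_dx = need_dx)
      gi$cv <- list(c1 = bdc$g$c1, c2 = bdc$g$c2,
                    dn = list(W = bdn$dW, b = bdn$db))
      if (need_dx) dxin <- add_or_set(dxin, bdc$dx)
    }
    if (cfg$transformer_branch) {
      bdn <- conv_bw(sc$tr$tcat, st$tr$dn$W, dtd, k = c(2, 2, 2), s = c(2, 2, 2),
                     p = c(0, 0, 0))
      sp <- split_c(bdn$dx, row$c_msa)
      bm1 <- msa_backward(sp[[1]], sc$tr$m1, st$tr$m1, row$stride, cfg$n_heads,
                          row$c_in, row$c_msa, need_dx = need_dx)
      bm2 <- msa_backward(sp[[2]], sc$tr$m2, st$tr$m2, row$stride, cfg$n_heads,
                          row$c_in, row$c_msa, need_dx = need_dx)
      gi$tr <- list(m1 = bm1$g, m2 = bm2$g, dn = list(W = bdn$dW, b = bdn$db))
      if (need_dx) {
        dxin <- add_or_set(dxin, bm1$dx)
        dxin <- add_or_set(dxin, bm2$dx)
      }
    }
    G$enc[[i]] <- gi
    if (i > 1L) dskips[[i - 1L]] <- add_or_set(dskips[[i - 1L]], dxin)
  }
  G
}

add_or_set <- function(a, b) if (is.null(a)) b else a + b

#' Encoder forward pass
#'
#' Runs only the dual-branch encoder, returning the per-stage skip feature
#' maps (the channel-concatenated, down-sampled branch outputs) and the
#' bottleneck map (the last skip).
#'
#' @param volume input `volume3d` or 3D array, dims divisible by the
#'   architecture's required multiple.
#' @param model a `uitrans_model` from [build_uitrans()].
#' @return list with `skips` (list of 4D `(d,h,w,c)` arrays, one per stage)
#'   and `bottleneck`.
#' @export
encoder_forward <- function(volume, model) {
  stopifnot(inherits(model, "uitrans_model"))
  x <- to4d(volume)
  if (!all(is.finite(x))) stop("non-finite values in input volume", call. = FALSE)
  check_input_shape(model, dim(x)[1:3])
  cfg <- model$config; P <- model$params; sched <- model$schedule
  skips <- vector("list", cfg$n_stages)
  for (i in seq_len(cfg$n_stages)) {
    row <- sched[i, ]
    st <- P$enc[[i]]
    parts <- list()
    if (cfg$conv_branch) {
      dc <- dconv_fw(x, st$cv)
      parts <- c(parts, list(conv_fw(dc$y, st$cv$dn$W, st$cv$dn$b,
                                     k = c(2, 2, 2), s = c(2, 2, 2), p = c(0, 0, 0))))
    }
    if (cfg$transformer_branch) {
      m1 <- msa_forward(x, st$tr$m1, row$stride, cfg$n_heads, row$c_msa)
      m2 <- msa_forward(x, st$tr$m2, row$stride, cfg$n_heads, row$c_msa)
      parts <- c(parts, list(conv_fw(concat_c(m1$y, m2$y), st$tr$dn$W, st$tr$dn$b,
                                     k = c(2, 2, 2), s = c(2, 2, 2), p = c(0, 0, 0))))
    }
    x <- if (length(parts) == 2L) concat_c(parts[[1]], parts[[2]]) else parts[[1]]
    skips[[i]] <- x
  }
  list(skips = skips, bottleneck = skips[[cfg$n_stages]])
}

#' Restore a volume with a model (direct forward pass)
#'
#' @inheritParams encoder_forward
#' @param clamp clamp output to `[0, 1]`; default follows the config's
#'   `final_activation`.
#' @return restored volume, same shape as the input.
#' @export
uitrans_restore <- function(model, volume, clamp = NULL) {
  stopifnot(inherits(model, "uitrans_model"))
  y <- uitrans_fw(model, volume, cache = FALSE,
                  apply_final = is.null(clamp))
  if (isTRUE(clamp)) y <- pmin(pmax(y, 0), 1)
  rewrap(y, if (inherits(volume, "volume3d")) volume else y)
}

#' Standalone multi-headed self-attention module
#'
#' Applies one seeded MSA module to a feature map: interval-extraction
#' tokenization, linear embedding, layer norm, multi-head self-attention
#' with a residual connection, a second layer norm, a token MLP with a
#' second residual, and re-assembly to the original spatial size.
#'
#' @param features 4D `(d, h, w, c)` array (or 3D array, treated as one
#'   channel).
#' @param n_heads attention heads; the embedding width must be divisible by
#'   it.
#' @param c_out output channels (default = input channels).
#' @param stride interval-extraction stride (must divide all spatial dims).
#' @param embed_mult embedding width multiplier.
#' @param mlp_ratio MLP hidden ratio.
#' @param seed parameter seed.
#' @return feature map `(d, h, w, c_out)` with an `"attention"` attribute
#'   holding the per-head token attention matrices.
#' @export
msa_module <- function(features, n_heads = 4L, c_out = NULL, stride = 2L,
                       embed_mult = 4L, mlp_ratio = 2, seed = 1) {
  x <- to4d(features)
  c_in <- channels4(x)
  if (is.null(c_out)) c_out <- c_in
  E <- embed_mult * c_out
  if (E %% n_heads != 0L)
    stop("invalid config: embedding width must be divisible by n_heads",
         call. = FALSE)
  if (any(dim(x)[1:3] %% stride != 0L))
    stop("spatial dims must be divisible by `stride`", call. = FALSE)
  pm <- with_seed(seed, msa_init(c_in, c_out, stride, E, mlp_ratio))
  out <- msa_forward(x, pm, stride, n_heads, c_out)
  structure(out$y, attention = out$cache$att$A)
}

#' Standalone transformer block (twin parallel MSA modules)
#'
#' Two parallel MSA modules with independent parameters, each emitting
#' `c_out / 2` channels, concatenated along channels so the block doubles
#' the channel width by default (matching the double-convolution block it
#' runs alongside). Spatial dims are unchanged.
#'
#' @inheritParams msa_module
#' @param c_out total output channels (default `2 * c_in`); must be even.
#' @param twin set `FALSE` to run a single MSA (debug/ablation), halving the
#'   output channels.
#' @return feature map `(d, h, w, c_out)` (or `c_out / 2` when
#'   `twin = FALSE`).
#' @export
transformer_block <- function(features, n_heads = 4L, c_out = NULL,
                              stride = 2L, embed_mult = 4L, mlp_ratio = 2,
                              seed = 1, twin = TRUE) {
  x <- to4d(features)
  if (is.null(c_out)) c_out <- 2L * channels4(x)
  if (c_out %% 2L != 0L) stop("`c_out` must be even", call. = FALSE)
  c_msa <- c_out %/% 2L
  E <- embed_mult * c_msa
  if (E %% n_heads != 0L)
    stop("invalid config: embedding width must be divisible by n_heads",
         call. = FALSE)
  m1 <- with_seed(child_seed(seed, 1L), msa_init(channels4(x), c_msa, stride, E,
                                                 mlp_ratio))
  o1 <- msa_forward(x, m1, stride, n_heads, c_msa)
  if (!twin) return(o1$y)
  m2 <- with_seed(child_seed(seed, 2L), msa_init(channels4(x), c_msa, stride, E,
                                                 mlp_ratio))
  o2 <- msa_forward(x, m2, stride, n_heads, c_msa)
  concat_c(o1$y, o2$y)
}
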