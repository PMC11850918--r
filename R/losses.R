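#' Training loss configuration
#'
#' The training objective is `L_total = L_MAE + lambda * L_perc`, the
#' volumetric mean absolute error plus a lambda-weighted perceptual loss
#' computed on 2D z-slices and averaged per volume. The default weight
#' `lambda = 0.01` balances the differing magnitudes of the two terms.
#'
#' The perceptual term measures the distance between activations of a
#' frozen 2D convolutional feature pyramid (VGG-style: stacked 3x3
#' convolutions with a stride-2 level). By default the extractor is a
#' fixed, seeded, randomly initialized network, which keeps the loss fully
#' deterministic and self-contained while preserving its structural-
#' similarity role; externally supplied pretrained weights can be plugged
#' in via `extractor_weights` to reproduce a classic pretrained-VGG
#' perceptual loss.
#'
#' @param lambda_weight perceptual weight, `>= 0` (default 0.01).
#' @param perceptual_layers which extractor levels enter the distance
#'   (default `c(2, 3)` of the 3 levels).
#' @param extractor_seed seed for the random frozen extractor.
#' @param extractor_channels channel widths of the 3 extractor levels.
#' @param extractor_weights optional externally supplied parameter tree (as
#'   produced by [build_perceptual_extractor()]), frozen as-is.
#' @param slice_axis axis along which volumes are sliced; only `"z"` (the
#'   x-y planes) is supported.
#' @return A `loss_config` object (the built frozen extractor is attached).
#' @export
loss_config <- function(lambda_weight = 0.01, perceptual_layers = c(2L, 3L),
                        extractor_seed = 7L, extractor_channels = c(8L, 16L, 16L),
                        extractor_weights = NULL, slice_axis = "z") {
  stopifnot_scalar_num(lambda_weight, "lambda_weight", min = 0)
  slice_axis <- match.arg(slice_axis, "z")
  ext <- extractor_weights %||%
    build_perceptual_extractor(extractor_seed, extractor_channels)
  perceptual_layers <- as.integer(perceptual_layers)
  if (any(perceptual_layers < 1L | perceptual_layers > length(ext$layers)))
    stop("perceptual_layers out of range", call. = FALSE)
  structure(list(lambda_weight = lambda_weight,
                 perceptual_layers = perceptual_layers,
                 extractor_seed = extractor_seed,
                 slice_axis = slice_axis, extractor = ext),
            class = "loss_config")
}

#' Frozen 2D perceptual feature extractor
#'
#' A small VGG-style 2D convolutional pyramid applied slice-wise: 3x3
#' convolutions (realized as 1x3x3 kernels over the z-stacked volume, so
#' every z-slice is processed independently and jointly), leaky-ReLU
#' activations, with a stride-2 spatial reduction at level 2. Single-channel
#' slices are replicated to three channels on input, the standard RGB
#' convention of pretrained perceptual networks. Parameters are drawn once
#' from `seed` and are never updated.
#'
#' @param seed initialization seed.
#' @param channels widths of the three levels.
#' @return extractor object: list of layer specs with weights.
#' @export
build_perceptual_extractor <- function(seed = 7L, channels = c(8L, 16L, 16L)) {
  stopifnot(length(channels) == 3L)
  with_seed(seed, {
    list(layers = list(
      list(p = init_conv_w(c(1, 3, 3), 3L, channels[1]),
           k = c(1L, 3L, 3L), s = c(1L, 1L, 1L), p3 = c(0L, 1L, 1L)),
      list(p = init_conv_w(c(1, 3, 3), channels[1], channels[2]),
           k = c(1L, 3L, 3L), s = c(1L, 2L, 2L), p3 = c(0L, 1L, 1L)),
      list(p = init_conv_w(c(1, 3, 3), channels[2], channels[3]),
           k = c(1L, 3L, 3L), s = c(1L, 1L, 1L), p3 = c(0L, 1L, 1L))),
      channels = channels)
  })
}

# Forward through the frozen extractor; returns activations per level plus
# pre-activation caches for input-gradient backprop.
perceptual_features <- function(v, ext, keep_cache = FALSE) {
  d <- dim(v)
  if (d[2] < 4L || d[3] < 4L)
    stop("slices must be at least 4 x 4 for the perceptual extractor",
         call. = FALSE)
  x <- array(0, c(d, 3L))
  x[, , , 1L] <- v; x[, , , 2L] <- v; x[, , , 3L] <- v
  feats <- vector("list", length(ext$layers))
  caches <- if (keep_cache) vector("list", length(ext$layers)) else NULL
  for (l in seq_along(ext$layers)) {
    ly <- ext$layers[[l]]
    pre <- conv_fw(x, ly$p$W, ly$p$b, k = ly$k, s = ly$s, p = ly$p3)
    act <- lrelu(pre)
    if (keep_cache) caches[[l]] <- list(x = x, pre = pre)
    feats[[l]] <- act
    x <- act
  }
  list(feats = feats, caches = caches)
}

#' Volumetric mean absolute error
#'
#' `mean(|V - V_hat|)` over all voxels: the pixel-level term of the training
#' objective.
#'
#' @param v,v_hat volumes of identical shape (restored output and ground
#'   truth; the loss is symmetric).
#' @return non-negative scalar.
#' @export
mae_loss <- function(v, v_hat) {
  a <- vol_values(v); b <- vol_values(v_hat)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: (%s) vs (%s)", paste(dim(a), collapse = ","),
                 paste(dim(b), collapse = ",")), call. = FALSE)
  mean(abs(a - b))
}

#' Slice-wise perceptual loss
#'
#' Splits both volumes into 2D z-slices, passes them through the frozen
#' feature extractor, and returns the mean squared difference of the
#' activations at the configured levels, averaged over slices (equivalently
#' over all activation elements, giving a per-volume mean). Zero iff the
#' extracted features are identical; symmetric.
#'
#' @inheritParams mae_loss
#' @param config a [loss_config()].
#' @return non-negative scalar.
#' @export
perceptual_loss <- function(v, v_hat, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  a <- vol_values(v); b <- vol_values(v_hat)
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch between volumes", call. = FALSE)
  fa <- perceptual_features(a, config$extractor)$feats
  fb <- perceptual_features(b, config$extractor)$feats
  mean(vapply(config$perceptual_layers,
              function(l) mean((fa[[l]] - fb[[l]])^2), 0))
}

#' Total mixed training loss
#'
#' `mae_loss(v, v_hat) + lambda_weight * perceptual_loss(v, v_hat, config)`.
#'
#' @inheritParams perceptual_loss
#' @return non-negative scalar with attributes `mae` and `perceptual`.
#' @export
total_loss <- function(v, v_hat, config = loss_config()) {
  m <- mae_loss(v, v_hat)
  p <- perceptual_loss(v, v_hat, config)
  structure(m + config$lambda_weight * p, mae = m, perceptual = p)
}

# Loss + gradient wrt the prediction, used by the trainer. `pred` is the
# network output, `target` the ground truth.
total_loss_grad <- function(pred, target, config) {
  d <- dim(pred)
  n <- length(pred)
  diff <- pred - target
  l_mae <- mean(abs(diff))
  g <- array(sign(diff) / n, d)
  l_perc <- 0
  if (config$lambda_weight > 0) {
    ext <- config$extractor
    fp <- perceptual_features(pred, ext, keep_cache = TRUE)
    ft <- perceptual_features(target, ext)
    sel <- config$perceptual_layers
    nl <- length(sel)
    dacts <- vector("list", length(ext$layers))
    for (l in sel) {
      dfe <- fp$feats[[l]] - ft$feats[[l]]
      l_perc <- l_perc + mean(dfe^2) / nl
      dacts[[l]] <- (2 / (length(dfe) * nl)) * dfe
    }
    dnext <- NULL
    for (l in rev(seq_along(ext$layers))) {
      dl <- dnext %||% array(0, dim(fp$feats[[l]]))
      if (!is.null(dacts[[l]])) dl <- dl + dacts[[l]]
      ly <- ext$layers[[l]]
      dpre <- dl * dlrelu(fp$caches[[l]]$pre)
      bw <- conv_bw(fp$caches[[l]]$x, ly$p$W, dpre, k = ly$k, s = ly$s,
                    p = ly$p3)
      dnext <- bw$dx
    }
    dchan <- dnext[, , , 1L] + dnext[, , , 2L] + dnext[, , , 3L]
    g <- g + config$lambda_weight * array(dchan, d)
  }
  list(loss = l_mae + config$lambda_weight * l_perc, mae = l_mae,
       perceptual = l_perc, grad = g)
}
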