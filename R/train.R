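#' Training configuration
#'
#' ADAM hyperparameters and data handling for network training. Full-scale
#' acquisitions train on 256^3 crops; the package default is the desk-scale
#' 32^3 so that a full training cycle runs in minutes on one CPU core.
#' Learning rate, schedule (constant) and epoch count are engineering
#' choices exposed here.
#'
#' @param learning_rate ADAM step size (default 1e-4).
#' @param beta1,beta2 ADAM moment decays (defaults 0.9 / 0.999).
#' @param epochs training epochs.
#' @param batch_size volumes per optimization step (gradients averaged).
#' @param patch_size 3-vector crop size; dims must be divisible by the
#'   architecture's required multiple.
#' @param patches_per_volume random co-located crops drawn per volume and
#'   epoch when volumes exceed `patch_size` (1 when they match).
#' @param split_ratio train:validation ratio (default `c(9, 1)`).
#' @param seed master seed for data order, splits and crops.
#' @param augment optional flips/axis rotations (default off).
#' @param max_steps hard cap on optimization steps (default unlimited).
#' @param stop_at_frac optional early-stopping fraction: training ends once
#'   the step loss falls below `stop_at_frac` times the first step's loss.
#' @param log_path optional JSON-lines file receiving one record per step
#'   (`step`, `L_MAE`, `L_vgg`, `L_total`, `lambda`).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epochs = 10L, batch_size = 1L,
                         patch_size = c(32L, 32L, 32L),
                         patches_per_volume = 1L,
                         split_ratio = c(9, 1), seed = 1L, augment = FALSE,
                         max_steps = Inf, stop_at_frac = NULL,
                         log_path = NULL) {
  stopifnot_scalar_num(learning_rate, "learning_rate", min = 1e-12)
  if (length(split_ratio) != 2L || any(split_ratio <= 0))
    stop("`split_ratio` parts must be positive", call. = FALSE)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 patches_per_volume = as.integer(patches_per_volume),
                 split_ratio = as.numeric(split_ratio), seed = as.integer(seed),
                 augment = isTRUE(augment), max_steps = max_steps,
                 stop_at_frac = stop_at_frac, log_path = log_path),
            class = "train_config")
}

#' Random train/validation split
#'
#' Disjoint, exhaustive split of a pair list in the given ratio (sizes
#' rounded, at least one volume per part), deterministic given `seed`.
#' 400 pairs at the default 9:1 give 360 train / 40 validation.
#'
#' @param pairs list of `paired_volume` (length `>= 2`).
#' @param ratio length-2 positive weights, train first.
#' @param seed integer seed.
#' @return list with `train` and `val` pair lists and the index vectors.
#' @export
split_dataset <- function(pairs, ratio = c(9, 1), seed = 1) {
  n <- length(pairs)
  if (n < 2L) stop("need at least 2 pairs to split", call. = FALSE)
  if (length(ratio) != 2L || any(ratio <= 0))
    stop("`ratio` must be 2 positive numbers", call. = FALSE)
  n_val <- round(n * ratio[2] / sum(ratio))
  n_val <- min(max(n_val, 1L), n - 1L)
  idx_val <- with_seed(seed, sort(sample.int(n, n_val)))
  idx_train <- setdiff(seq_len(n), idx_val)
  list(train = pairs[idx_train], val = pairs[idx_val],
       train_idx = idx_train, val_idx = idx_val)
}

#' Extract co-located patch pairs
#'
#' Draws `n` random crops at identical corner coordinates from the input
#' and ground-truth volumes of a pair, deterministic given `seed`. When the
#' patch equals the volume shape the single full-volume crop is returned.
#'
#' @param pair a `paired_volume`.
#' @param patch_size 3-vector, each dim `<=` the volume shape.
#' @param n number of crops.
#' @param seed integer seed.
#' @return list of `paired_volume` crops; each carries a `corner` field.
#' @export
extract_patches <- function(pair, patch_size, n = 1L, seed = 1) {
  stopifnot(inherits(pair, "paired_volume"))
  d <- dim(pair$input)
  patch_size <- as.integer(patch_size)
  if (any(patch_size > d))
    stop(sprintf("patch (%s) larger than volume (%s)",
                 paste(patch_size, collapse = ","), paste(d, collapse = ",")),
         call. = FALSE)
  room <- d - patch_size
  corners <- with_seed(seed, {
    lapply(seq_len(n), function(i)
      c(sample.int(room[1] + 1L, 1L), sample.int(room[2] + 1L, 1L),
        sample.int(room[3] + 1L, 1L)))
  })
  lapply(corners, function(cr) {
    take <- function(v) {
      vv <- vol_values(v)[cr[1]:(cr[1] + patch_size[1] - 1L),
                          cr[2]:(cr[2] + patch_size[2] - 1L),
                          cr[3]:(cr[3] + patch_size[3] - 1L), drop = FALSE]
      rewrap(vv, v)
    }
    out <- structure(list(input = take(pair$input),
                          ground_truth = take(pair$ground_truth),
                          input_params = pair$input_params,
                          gt_params = pair$gt_params, seed = pair$seed),
                     class = "paired_volume")
    out$corner <- cr
    out
  })
}

augment_pair <- function(xin, xgt, code) {
  flip <- function(v, a) {
    idx <- list(TRUE, TRUE, TRUE); idx[[a]] <- rev(seq_len(dim(v)[a]))
    do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  }
  for (a in 1:3) if (bitwAnd(code, 2^(a - 1)) > 0) {
    xin <- flip(xin, a); xgt <- flip(xgt, a)
  }
  list(xin, xgt)
}

# Core training loop on normalized patch pairs. Returns a train-state with
# per-epoch records, step losses, and best-validation parameters.
uitrans_train <- function(model, train_pairs, val_pairs, loss_cfg, tc,
                          verbose = FALSE) {
  max_steps <- tc$max_steps %||% Inf
  stop_at_frac <- tc$stop_at_frac
  n_tr <- length(train_pairs)
  if (n_tr < 1L) stop("need at least one training pair", call. = FALSE)
  opt <- adam_init(model$params)
  ext0 <- unlist(tree_leaves(loss_cfg$extractor$layers))
  step <- 0L
  step_log <- list()
  records <- list()
  best <- list(val = Inf, params = model$params, epoch = 0L)
  logcon <- if (!is.null(tc$log_path)) file(tc$log_path, open = "wt") else NULL
  on.exit(if (!is.null(logcon)) close(logcon))
  first_loss <- NA_real_
  for (ep in seq_len(tc$epochs)) {
    ord <- with_seed(child_seed(tc$seed, 1000L + ep), sample.int(n_tr))
    ep_losses <- c()
    for (ii in seq_along(ord)) {
      pr <- train_pairs[[ord[ii]]]
      crops <- if (all(dim(pr$input) == tc$patch_size)) list(pr) else
        extract_patches(pr, tc$patch_size, tc$patches_per_volume,
                        child_seed(tc$seed, 2000L + ep * n_tr + ii))
      for (cp in crops) {
        xin <- vol_values(cp$input); xgt <- vol_values(cp$ground_truth)
        if (tc$augment) {
          code <- with_seed(child_seed(tc$seed, 3000L + step), sample.int(8L, 1L) - 1L)
          au <- augment_pair(xin, xgt, code); xin <- au[[1]]; xgt <- au[[2]]
        }
        fw <- uitrans_fw(model, xin, cache = TRUE)
        lg <- total_loss_grad(fw$y, xgt, loss_cfg)
        if (!is.finite(lg$loss))
          stop(sprintf(
            "NaN/Inf loss at epoch %d, pair index %d (step %d): aborting",
            ep, ord[ii], step + 1L), call. = FALSE)
        G <- uitrans_bw(model, fw$cache, lg$grad)
        up <- adam_step(model$params, G, opt, tc$learning_rate, tc$beta1, tc$beta2)
        model$params <- up$params; opt <- up$state
        step <- step + 1L
        if (is.na(first_loss)) first_loss <- lg$loss
        ep_losses <- c(ep_losses, lg$loss)
        rec <- list(step = step, L_MAE = lg$mae, L_vgg = lg$perceptual,
                    L_total = lg$loss, lambda = loss_cfg$lambda_weight)
        step_log[[step]] <- rec
        if (!is.null(logcon))
          writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), logcon)
        if (verbose && step %% 20L == 0L)
          message(sprintf("step %d  L_total %.5f (MAE %.5f)", step, lg$loss, lg$mae))
        if (!is.null(stop_at_frac) && lg$loss <= stop_at_frac * first_loss)
          max_steps <- min(max_steps, step)
        if (step >= max_steps) break
      }
      if (step >= max_steps) break
    }
    val_loss <- NA_real_
    if (length(val_pairs) > 0L) {
      vls <- vapply(val_pairs, function(vp) {
        y <- uitrans_fw(model, vol_values(vp$input), cache = FALSE,
                        apply_final = FALSE)
        as.numeric(total_loss(y, vol_values(vp$ground_truth), loss_cfg))
      }, 0)
      val_loss <- mean(vls)
      if (val_loss < best$val) best <- list(val = val_loss, params = model$params,
                                            epoch = ep)
    }
    records[[ep]] <- data.frame(epoch = ep,
                                train_loss = mean(ep_losses),
                                val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %d  train %.5f  val %.5f", ep,
                      mean(ep_losses), val_loss))
    if (step >= max_steps) break
  }
  if (!is.finite(best$val)) best <- list(val = NA_real_, params = model$params,
                                         epoch = tc$epochs)
  stopifnot(identical(ext0, unlist(tree_leaves(loss_cfg$extractor$layers))))
  steps_df <- do.call(rbind, lapply(step_log, as.data.frame))
  list(model = model, best_params = best$params, best_epoch = best$epoch,
       best_val = best$val,
       records = if (length(records)) do.call(rbind, records) else
         data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric()),
       steps = steps_df, n_steps = step)
}

#' Fit the restoration network to paired volumes
#'
#' The front door of the package: takes simulated (or loaded) aligned
#' input/ground-truth pairs, percentile-normalizes each volume to `[0, 1]`,
#' splits them into training and validation sets (default 9:1), and trains
#' the dual-branch network with ADAM on the mixed MAE + perceptual
#' objective. Returns a fitted-model object with the usual methods
#' ([predict.uitrans()], `print`, `summary`, `plot`, `coef`).
#'
#' @param pairs list of `paired_volume` objects (length `>= 2`; use a list
#'   of one pair plus `split = FALSE` for overfit experiments).
#' @param config a [uitrans_config()]; default is the desk-scale preset.
#' @param loss a [loss_config()].
#' @param train a [train_config()].
#' @param seed model initialization seed.
#' @param split set `FALSE` to train on all pairs without validation.
#' @param normalize percentile-normalize volumes before training (default
#'   TRUE; recorded in the object).
#' @param verbose print per-epoch progress.
#' @return An object of class `uitrans`.
#' @export
uitrans <- function(pairs, config = uitrans_config_desk(),
                    loss = loss_config(), train = train_config(),
                    seed = 1, split = TRUE, normalize = TRUE,
                    verbose = FALSE) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  norm_fun <- if (normalize) function(v) normalize_volume(v) else identity
  prep <- lapply(pairs, function(p) {
    p$input <- norm_fun(p$input); p$ground_truth <- norm_fun(p$ground_truth); p
  })
  if (split && length(prep) >= 2L) {
    sp <- split_dataset(prep, train$split_ratio, child_seed(train$seed, 11L))
  } else {
    sp <- list(train = prep, val = list(), train_idx = seq_along(prep),
               val_idx = integer())
  }
  model <- build_uitrans(config, seed = seed)
  st <- uitrans_train(model, sp$train, sp$val, loss, train, verbose = verbose)
  fit <- structure(list(
    model = structure(list(params = st$best_params, config = config,
                           seed = seed, schedule = model$schedule,
                           n_params = model$n_params),
                      class = "uitrans_model"),
    final_model = st$model,
    history = st$records, steps = st$steps, n_steps = st$n_steps,
    best_epoch = st$best_epoch, best_val = st$best_val,
    loss_config = loss, train_config = train,
    normalize = normalize, split = sp[c("train_idx", "val_idx")],
    call = match.call()), class = "uitrans")
  fit
}

#' @export
print.uitrans <- function(x, ...) {
  cat("Dual-branch CNN-transformer restoration fit\n")
  print(x$model)
  cat(sprintf("  trained %d steps over %d epochs; best val loss %.5g (epoch %d)\n",
              x$n_steps, nrow(x$history), x$best_val, x$best_epoch))
  cat(sprintf("  train/val volumes: %d / %d\n", length(x$split$train_idx),
              length(x$split$val_idx)))
  invisible(x)
}

#' @export
summary.uitrans <- function(object, ...) {
  cat("Architecture schedule (channels per stage):\n")
  print(object$model$schedule, row.names = FALSE)
  print(object)
  if (nrow(object$history)) {
    cat("Loss history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Restore volumes with a fitted model
#'
#' Applies the trained network to a new volume. Inputs are
#' percentile-normalized exactly as during training (when the fit was
#' normalized). Volumes whose dimensions are not divisible by the
#' architecture's required multiple, or that exceed `tile`, are restored by
#' [tiled_restore()].
#'
#' @param object a `uitrans` fit.
#' @param newdata a `volume3d` / 3D array.
#' @param tile optional tile size for tiled inference.
#' @param overlap tile overlap in voxels.
#' @param clamp clamp the output to `[0, 1]` (default TRUE: restored
#'   fluorescence intensities are non-negative).
#' @param ... unused.
#' @return restored volume.
#' @export
predict.uitrans <- function(object, newdata, tile = NULL, overlap = 8L,
                            clamp = TRUE, ...) {
  v <- if (object$normalize) normalize_volume(newdata) else newdata
  x <- vol_values(v)
  req <- required_multiple(object$model$config)
  need_tiling <- !is.null(tile) || any(dim(x) %% req != 0L)
  y <- if (need_tiling) {
    tile <- tile %||% pmin(dim(x) + (req - dim(x) %% req) %% req, 64L)
    tiled_restore(object$model, x, tile = tile, overlap = overlap)
  } else {
    uitrans_fw(object$model, x, cache = FALSE, apply_final = FALSE)
  }
  if (clamp) y <- pmin(pmax(y, 0), 1)
  rewrap(y, newdata)
}

#' @export
coef.uitrans <- function(object, ...) {
  lv <- tree_leaves(object$model$params)
  unlist(lv, use.names = FALSE)
}

#' Plot the training loss history
#'
#' @param x a `uitrans` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.uitrans <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no training history"); return(invisible(x)) }
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch",
                    ylab = expression(L[total]),
                    main = "Training history", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS archive holding the parameter tree, the
#' full architecture configuration, seeds and the normalization flag, plus
#' a hash of the configuration that is verified on load.
#'
#' @param fit a `uitrans` fit or a bare `uitrans_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `uitrans_model` (with `normalize` attribute when saved from
#'   a fit).
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "uitrans")) fit$model else fit
  stopifnot(inherits(model, "uitrans_model"))
  payload <- list(params = model$params, config = unclass(model$config),
                  seed = model$seed,
                  normalize = if (inherits(fit, "uitrans")) fit$normalize else NA,
                  hash = config_hash(unclass(model$config)))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$hash, config_hash(payload$config)))
    stop("checkpoint config hash mismatch: file corrupted or incompatible",
         call. = FALSE)
  cfg <- do.call(uitrans_config, payload$config[setdiff(names(payload$config),
                                                        character())])
  model <- structure(list(params = payload$params, config = cfg,
                          seed = payload$seed,
                          schedule = uitrans_schedule(cfg)),
                     class = "uitrans_model")
  model$n_params <- count_parameters(model)
  attr(model, "normalize") <- payload$normalize
  model
}
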