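# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Lehmer generator reproducible bit-for-bit across languages; used where
# frozen oracle values were computed with an independent implementation.
lehmer_seq <- function(seed, n) {
  x <- seed
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (48271 * x) %% 2147483647
    out[i] <- x / 2147483647
  }
  out
}

# tiny dual-branch model config for fast architecture/gradient tests
tiny_config <- function(...) {
  uitrans_config(n_stages = 2L, base_channels = 2L, n_heads = 2L,
                 token_stride = 1L, ...)
}

# chamber geometry spanning the full z-range, as in an acquisition cropped
# to the organ: every slice carries cardiac signal for synchronization
z_spanning_geometry <- function() {
  list(centers = rbind(c(0.42, 0.20, 0.12), c(-0.44, -0.26, -0.20)),
       radii = rbind(c(0.52, 0.42, 0.40), c(0.50, 0.30, 0.28)))
}

small_phantom_pair <- function(shape = c(32, 32, 32), seed = 3) {
  fixture(paste0("pair", paste(shape, collapse = "x"), "_", seed), function() {
    ph <- generate_heart_phantom(shape, seed = 2)
    make_training_pair(ph, seed = seed, store_phantom = TRUE)
  })
}

# Desk-scale restoration pipeline: 40 simulated pairs at 32^3, 9:1 split,
# the documented training schedule. Cached so the headline property test,
# the tiled-inference consistency test and the acceptance block share one
# training run.
desk_pipeline <- function() {
  fixture("desk_pipeline", function() {
    pairs <- simulate_training_pairs(40L, c(32L, 32L, 32L), seed = 20260926)
    fit <- uitrans(pairs,
                   config = uitrans_config_desk(),
                   loss = loss_config(),
                   train = train_config(learning_rate = 1e-3, epochs = 5L,
                                        patch_size = c(32L, 32L, 32L),
                                        split_ratio = c(9, 1), seed = 101L),
                   seed = 7L)
    val_pairs <- pairs[fit$split$val_idx]
    metrics <- lapply(val_pairs, function(p) {
      vin <- normalize_volume(p$input)
      vgt <- normalize_volume(p$ground_truth)
      vres <- predict(fit, p$input)
      masks <- otsu_masks(vgt)
      list(snr_in = as.numeric(compute_snr_db(vin, masks$fg, masks$bg)),
           snr_res = as.numeric(compute_snr_db(vres, masks$fg, masks$bg)),
           nrmse_in = compute_nrmse(vin, vgt),
           nrmse_res = compute_nrmse(vres, vgt),
           pear_in = compute_pearson(vin, vgt),
           pear_res = compute_pearson(vres, vgt))
    })
    list(fit = fit, pairs = pairs, val_pairs = val_pairs,
         metrics = do.call(rbind, lapply(metrics, as.data.frame)))
  })
}
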