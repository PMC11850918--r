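# An identity-trained local (conv-only) model: the operator for which tiled
# and whole-volume inference should closely agree.
identity_fit <- function() {
  fixture("identity_fit", function() {
    ph <- normalize_volume(generate_heart_phantom(c(16, 16, 16), seed = 31))
    pr <- structure(list(input = ph, ground_truth = ph,
                         input_params = lsfm_economy_params(),
                         gt_params = lsfm_quality_params(), seed = 1L),
                    class = "paired_volume")
    uitrans(list(pr),
            config = uitrans_config(n_stages = 2L, base_channels = 4L,
                                    transformer_branch = FALSE),
            loss = loss_config(lambda_weight = 0),
            train = train_config(learning_rate = 1e-3, epochs = 200L,
                                 patch_size = c(16L, 16L, 16L), seed = 2L,
                                 max_steps = 200L),
            seed = 3, split = FALSE, normalize = FALSE)
  })
}

test_that("a single covering tile reproduces the direct forward pass exactly", {
  fit <- identity_fit()
  v <- vol_values(normalize_volume(generate_heart_phantom(c(32, 32, 32),
                                                          seed = 32)))
  direct <- uitrans:::uitrans_fw(fit$model, v, cache = FALSE,
                                 apply_final = FALSE)
  tl <- tiled_restore(fit$model, v, tile = c(32, 32, 32), overlap = 8L)
  expect_lt(max(abs(tl - direct)), 1e-12)
})

test_that("volumes smaller than one tile are padded, restored and cropped back", {
  fit <- identity_fit()
  v <- vol_values(normalize_volume(generate_heart_phantom(c(32, 32, 32),
                                                          seed = 32)))
  v12 <- v[1:12, 1:12, 1:12]
  out <- tiled_restore(fit$model, v12, tile = c(16, 16, 16), overlap = 4L)
  expect_identical(dim(out), c(12L, 12L, 12L))
  expect_true(all(is.finite(out)))
  # identity-trained model: the restored crop should stay close to the input
  expect_lt(mean(abs(out - v12)), 0.1)
})

test_that("tile mosaics agree with whole-volume restoration up to seam error", {
  fit <- identity_fit()
  v <- vol_values(normalize_volume(generate_heart_phantom(c(32, 32, 32),
                                                          seed = 32)))
  direct <- uitrans:::uitrans_fw(fit$model, v, cache = FALSE,
                                 apply_final = FALSE)
  tl <- tiled_restore(fit$model, v, tile = c(16, 16, 16), overlap = 4L)
  # a local identity-like operator: blending seams contribute only a small
  # RMS discrepancy (context truncation at tile borders is irreducible)
  expect_lt(sqrt(mean((tl - direct)^2)), 0.02)
  expect_lt(max(abs(tl - direct)), 0.2)
})

test_that("cosine tile windows are symmetric ramps forming a valid cover", {
  w <- uitrans:::tile_window(16L, 4L)
  expect_identical(w, rev(w))
  expect_true(all(w > 0 & w <= 1))
  expect_identical(w[5:12], rep(1, 8))
  # adjacent tiles at stride tile - overlap: ramps cross at 1/2 and their
  # pre-normalization sum stays bounded away from zero everywhere
  step <- 12L
  cover <- numeric(16L + step)
  cover[1:16] <- cover[1:16] + w
  cover[step + (1:16)] <- cover[step + (1:16)] + w
  expect_true(all(cover[5:(step + 12)] > 0.49))
})

test_that("restoration is translation-consistent away from borders", {
  fit <- identity_fit()
  v <- vol_values(normalize_volume(generate_heart_phantom(c(32, 32, 32),
                                                          seed = 32)))
  direct <- uitrans:::uitrans_fw(fit$model, v, cache = FALSE,
                                 apply_final = FALSE)
  for (s in list(c(4L, 0L, 0L), c(0L, 8L, 4L))) {
    vs <- uitrans:::translate_volume(v, s, pad = median(v))
    ys <- uitrans:::uitrans_fw(fit$model, vs, cache = FALSE,
                               apply_final = FALSE)
    ds <- uitrans:::translate_volume(direct, s, pad = 0)
    m <- 10L
    inner <- function(a) a[(1 + m):(32 - m), (1 + m):(32 - m), (1 + m):(32 - m)]
    expect_lt(max(abs(inner(ys) - inner(ds))), 0.02)
  }
})

test_that("predict() handles volumes with indivisible dimensions via tiling", {
  pl <- desk_pipeline()
  ph <- generate_heart_phantom(c(36, 36, 36), seed = 55)
  pr <- make_training_pair(ph, seed = 56)
  out <- predict(pl$fit, pr$input, tile = c(32, 32, 32), overlap = 8L)
  expect_identical(dim(out), c(36L, 36L, 36L))
  expect_true(all(out >= 0 & out <= 1))
  # restored quality beats the raw input against the clean reference
  gt <- normalize_volume(pr$ground_truth)
  expect_gt(compute_pearson(out, gt),
            compute_pearson(normalize_volume(pr$input), gt))
})

test_that("invalid tiling parameters are rejected", {
  fit <- identity_fit()
  v <- array(runif(16^3), c(16, 16, 16))
  expect_error(tiled_restore(fit$model, v, tile = c(15, 16, 16)), "divisible")
  expect_error(tiled_restore(fit$model, v, tile = c(16, 16, 16), overlap = 8L),
               "overlap")
})
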