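test_that("PSF blur preserves constants, flux, and has the right widths", {
  p <- degradation_params()
  const <- volume3d(array(0.4, c(16, 16, 16)))
  out <- apply_psf(const, p)
  expect_equal(as.vector(unclass(out)), rep(0.4, 16^3), tolerance = 1e-12)

  # interior flux conservation within 1% on a centered blob
  ph <- generate_heart_phantom(c(32, 32, 32), seed = 1)
  blurred <- apply_psf(ph, p)
  expect_equal(sum(unclass(blurred)), sum(unclass(ph)), tolerance = 0.01)

  # second moments of a centered impulse match the requested sigmas (voxels)
  imp <- array(0, c(33, 33, 33)); imp[17, 17, 17] <- 1
  vz <- 1; sig_z <- 2; sig_xy <- 1
  pp <- degradation_params(lateral_sigma_um = sig_xy, axial_sigma_um = sig_z)
  out <- unclass(apply_psf(volume3d(imp, c(1, 1, 1)), pp))
  coords <- seq_len(33) - 17
  mz <- apply(out, 1, sum); my <- apply(out, 2, sum); mx <- apply(out, 3, sum)
  var_z <- sum(coords^2 * mz) / sum(mz)
  var_y <- sum(coords^2 * my) / sum(my)
  var_x <- sum(coords^2 * mx) / sum(mx)
  expect_equal(var_z, sig_z^2, tolerance = 0.05)
  expect_equal(var_y, sig_xy^2, tolerance = 0.05)
  expect_equal(var_x, sig_xy^2, tolerance = 0.05)
})

test_that("scatter haze follows its additive closed form", {
  ph <- generate_heart_phantom(c(24, 24, 24), seed = 2)
  p0 <- degradation_params(haze_strength = 0, background_offset = 0.1)
  out0 <- add_scatter_haze(ph, p0)
  expect_equal(unclass(out0), unclass(ph) + 0.1, tolerance = 1e-12,
               ignore_attr = TRUE)

  # perfect confocal rejection is equivalent to zero haze
  prj <- degradation_params(haze_strength = 2, confocal_rejection = 0,
                            background_offset = 0.1)
  expect_equal(unclass(add_scatter_haze(ph, prj)), unclass(out0),
               tolerance = 1e-12, ignore_attr = TRUE)

  # normalized kernel: total intensity scales by (1 + strength) within 2%
  ph_small <- generate_heart_phantom(c(32, 32, 32), seed = 3,
                                     geometry = list(background = 0))
  ph5 <- degradation_params(haze_strength = 0.5, confocal_rejection = 1,
                            background_offset = 0)
  hz <- add_scatter_haze(ph_small, ph5)
  expect_equal(sum(unclass(hz)), 1.5 * sum(unclass(ph_small)),
               tolerance = 0.02)
})

test_that("Poisson-Gaussian noise has the predicted mean-variance law", {
  zero <- volume3d(array(0, c(8, 8, 8)))
  p0 <- degradation_params(photon_gain = 100, read_sigma = 0)
  expect_true(all(unclass(add_noise(zero, p0, seed = 1)) == 0))

  p <- degradation_params(photon_gain = 100, read_sigma = 0.02)
  const <- volume3d(array(0.5, c(100, 100, 100)))
  noisy <- unclass(add_noise(const, p, seed = 11))
  expect_equal(mean(noisy), 0.5, tolerance = 0.01)
  expect_equal(var(as.vector(noisy)), 0.5 / 100 + 0.02^2, tolerance = 0.03)

  # seeded determinism
  expect_identical(unclass(add_noise(const, p, seed = 4)),
                   unclass(add_noise(const, p, seed = 4)))
  expect_warning(add_noise(volume3d(array(-0.1, c(4, 4, 4))), p, 1), "clamp")
})

test_that("training pairs are aligned, reproducible, and GT is cleaner", {
  ph <- generate_heart_phantom(c(24, 24, 24), seed = 5)
  pr1 <- make_training_pair(ph, seed = 9)
  pr2 <- make_training_pair(ph, seed = 9)
  expect_identical(unclass(pr1$input), unclass(pr2$input))
  expect_identical(unclass(pr1$ground_truth), unclass(pr2$ground_truth))
  expect_identical(dim(pr1$input), dim(pr1$ground_truth))

  # noiseless, haze-free GT arm reduces to the blurred phantom
  clean <- degradation_params(haze_strength = 0, confocal_rejection = 0,
                              photon_gain = Inf, read_sigma = 0,
                              background_offset = 0)
  pr <- suppressWarnings(make_training_pair(ph, gt_params = clean, seed = 1))
  expect_equal(unclass(pr$ground_truth),
               unclass(apply_psf(as_volume3d(ph), lsfm_economy_params())),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a GT arm that is not cleaner triggers a warning
  expect_warning(make_training_pair(ph, input_params = lsfm_quality_params(),
                                    gt_params = lsfm_economy_params(),
                                    seed = 1), "cleaner")
})

test_that("economy input is worse than quality GT across seeds", {
  worse_snr <- worse_contrast <- logical(20)
  for (i in 1:20) {
    ph <- generate_heart_phantom(c(24, 24, 24), seed = 100 + i)
    pr <- make_training_pair(ph, seed = 200 + i)
    gt_n <- normalize_volume(pr$ground_truth)
    in_n <- normalize_volume(pr$input)
    masks <- otsu_masks(gt_n)
    worse_snr[i] <- as.numeric(compute_snr_db(in_n, masks$fg, masks$bg)) <
      as.numeric(compute_snr_db(gt_n, masks$fg, masks$bg))
    cm <- function(v) (mean(v[masks$fg]) - mean(v[masks$bg])) /
      (mean(v[masks$fg]) + mean(v[masks$bg]))
    worse_contrast[i] <- cm(unclass(in_n)) < cm(unclass(gt_n))
  }
  expect_gte(mean(worse_snr), 0.95)
  expect_gte(mean(worse_contrast), 0.95)
})

test_that("SNR degrades monotonically with read noise and improves with photons", {
  ph <- generate_heart_phantom(c(24, 24, 24), seed = 7)
  snr_of <- function(gain, read) {
    p <- degradation_params(photon_gain = gain, read_sigma = read,
                            haze_strength = 0, background_offset = 0)
    noisy <- add_noise(apply_psf(ph, p), p, seed = 33)
    masks <- otsu_masks(apply_psf(ph, p))
    as.numeric(compute_snr_db(noisy, masks$fg, masks$bg))
  }
  by_read <- sapply(c(0.01, 0.05, 0.2), function(r) snr_of(100, r))
  expect_true(all(diff(by_read) <= 0))
  by_gain <- sapply(c(5, 50, 500), function(g) snr_of(g, 0.01))
  expect_true(all(diff(by_gain) >= 0))
})

test_that("pairs round-trip through TIFF + JSON sidecars", {
  ph <- generate_heart_phantom(c(12, 12, 12), seed = 5)
  pr <- make_training_pair(ph, seed = 9)
  pr$input <- normalize_volume(pr$input)
  pr$ground_truth <- normalize_volume(pr$ground_truth)
  dir <- withr::local_tempdir()
  write_training_pair(pr, dir, "p1")
  back <- read_training_pair(dir, "p1")
  expect_equal(unclass(back$input), unclass(pr$input), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$input_params$photon_gain, pr$input_params$photon_gain)
})
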