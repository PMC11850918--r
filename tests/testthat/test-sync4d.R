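test_that("period estimation recovers a known sinusoid period", {
  t <- seq_len(1000)
  trace <- sin(2 * pi * t / 75)
  est <- estimate_period(trace)
  expect_lte(abs(as.integer(est) - 75L), 1L)
  expect_error(estimate_period(rep(1, 100)), "aperiodic")
  expect_error(estimate_period(array(0.5, c(50, 4, 4))), "aperiodic")
})

test_that("period estimation is robust to noise across seeds", {
  t <- seq_len(1000)
  ok <- logical(20)
  for (i in 1:20) {
    set.seed(700 + i)
    trace <- sin(2 * pi * t / 75) + rnorm(1000, 0, 0.1)
    ok[i] <- abs(as.integer(estimate_period(trace)) - 75L) <= 1L
  }
  expect_gte(mean(ok), 0.95)
})

beating_movie_fixture <- function(noise_sd = 0) {
  fixture(paste0("movies", noise_sd), function() {
    ph <- generate_heart_phantom(c(20, 24, 24), seed = 4,
                                 geometry = z_spanning_geometry())
    beat <- suppressWarnings(deform_beating(ph, n_frames = 10L,
                                            period_frames = 10L,
                                            amplitude = 0.08))
    make_slice_movies(beat, T_frames = 40L, noise_sd = noise_sd, seed = 17)
  })
}

test_that("per-slice phase offsets are recovered up to the phase gauge", {
  mset <- beating_movie_fixture()
  hb <- suppressWarnings(synchronize_movies(mset,
                                            period_frames = mset$period_frames))
  p <- mset$period_frames
  diffs <- (hb$offsets - mset$true_offsets) %% p
  # circular distance to the dominant gauge constant
  gauge <- as.integer(names(sort(table(diffs), decreasing = TRUE))[1])
  circ <- pmin((diffs - gauge) %% p, (gauge - diffs) %% p)
  expect_gte(mean(circ <= 1), 0.95)
})

test_that("synchronized phase volumes match the generating cycle", {
  mset <- beating_movie_fixture()
  ph <- generate_heart_phantom(c(20, 24, 24), seed = 4,
                               geometry = z_spanning_geometry())
  beat <- suppressWarnings(deform_beating(ph, n_frames = 10L,
                                          period_frames = 10L,
                                          amplitude = 0.08))
  hb <- suppressWarnings(synchronize_movies(mset, period_frames = 10L))
  p <- 10L
  # account for the global phase gauge: find the cyclic rotation that best
  # matches phase 0, then demand Pearson >= 0.95 there
  cors <- sapply(0:(p - 1L), function(r)
    compute_pearson(hb$volumes[[r + 1L]], beat$frames[[1L]]))
  expect_gte(max(cors), 0.95)
})

test_that("in-phase movies reconstruct by identity reordering", {
  ph <- generate_heart_phantom(c(12, 16, 16), seed = 6,
                               geometry = z_spanning_geometry())
  beat <- suppressWarnings(deform_beating(ph, n_frames = 8L,
                                          period_frames = 8L,
                                          amplitude = 0.08))
  mset <- make_slice_movies(beat, T_frames = 24L, offsets = rep(0L, 12L))
  hb <- suppressWarnings(synchronize_movies(mset, period_frames = 8L))
  expect_identical(hb$offsets, rep(0L, 12L))
  for (phi in 1:8)
    expect_equal(hb$volumes[[phi]], beat$frames[[phi]], tolerance = 1e-12)
})

test_that("adding a constant to all offsets cyclically rotates the output", {
  ph <- generate_heart_phantom(c(12, 16, 16), seed = 7,
                               geometry = z_spanning_geometry())
  beat <- suppressWarnings(deform_beating(ph, n_frames = 8L,
                                          period_frames = 8L,
                                          amplitude = 0.08))
  base_off <- c(0L, 3L, 5L, 1L, 7L, 2L, 4L, 6L, 0L, 5L, 2L, 3L)
  m1 <- make_slice_movies(beat, T_frames = 24L, offsets = base_off)
  m2 <- make_slice_movies(beat, T_frames = 24L, offsets = (base_off + 3L) %% 8L)
  h1 <- suppressWarnings(synchronize_movies(m1, period_frames = 8L))
  h2 <- suppressWarnings(synchronize_movies(m2, period_frames = 8L))
  # movies of set 2 lead set 1 by 3 frames, so phase bin k of h2 equals
  # phase bin (k + 3) mod 8 of h1
  match_rot <- sapply(0:7, function(r) {
    all(sapply(1:8, function(k)
      isTRUE(all.equal(h2$volumes[[k]],
                       h1$volumes[[((k - 1L + r) %% 8L) + 1L]],
                       tolerance = 1e-12))))
  })
  expect_true(any(match_rot))
})

test_that("period estimation and synchronization work from movie stacks end to end", {
  mset <- beating_movie_fixture(noise_sd = 0.02)
  est <- estimate_period(mset$movies[[which.max(sapply(mset$movies, sd))]])
  expect_lte(abs(as.integer(est) - 10L), 1L)
  hb <- suppressWarnings(synchronize_movies(mset, period_frames = NULL))
  expect_lte(abs(hb$period_frames - 10L), 1L)
  expect_length(hb$volumes, hb$period_frames)
})
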