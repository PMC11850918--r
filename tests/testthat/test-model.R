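test_that("seeded initialization is reproducible and counted correctly", {
  cfg <- tiny_config()
  a <- build_uitrans(cfg, seed = 11)
  b <- build_uitrans(cfg, seed = 11)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, build_uitrans(cfg, seed = 12)$params))

  # independent layer-by-layer parameter tally from the channel schedule
  tally <- function(cfg) {
    n <- cfg$n_stages; base <- cfg$base_channels
    branches <- cfg$conv_branch + cfg$transformer_branch
    conv_p <- function(k, ci, co) k^3 * ci * co + co
    msa_p <- function(ci, co, s, E, mlp) {
      H <- round(mlp * E)
      (s^3 * ci) * E + E +          # embedding
        2 * E + 2 * E +             # two layer norms
        4 * (E * E + E) +           # Wq, Wk, Wv, Wo + biases
        E * H + H + H * E + E +     # MLP
        E * (s^3 * co) + s^3 * co   # output projection
    }
    total <- 0
    c_in <- 1
    widths <- numeric(n)
    for (i in seq_len(n)) {
      c_out <- base * 2^i; c_msa <- c_out / 2
      s <- cfg$token_stride * 2^(n - i); E <- cfg$embed_mult * c_msa
      if (cfg$conv_branch)
        total <- total + conv_p(3, c_in, c_out) + conv_p(3, c_out, c_out) +
          conv_p(2, c_out, c_out)
      if (cfg$transformer_branch)
        total <- total + 2 * msa_p(c_in, c_msa, s, E, cfg$mlp_ratio) +
          conv_p(2, c_out, c_out)
      widths[i] <- branches * c_out
      c_in <- widths[i]
    }
    x_ch <- widths[n]
    if (n > 1) for (j in seq_len(n - 1)) {
      i <- n - j; co <- base * 2^i
      total <- total + conv_p(3, x_ch, co) + conv_p(3, co + widths[i], co) +
        conv_p(3, co, co)
      x_ch <- co
    }
    total + conv_p(3, x_ch, base) + conv_p(3, base, base) + conv_p(1, base, 1)
  }
  expect_identical(count_parameters(a), as.integer(tally(cfg)))
  dflt <- uitrans_config()
  expect_identical(build_uitrans(dflt, seed = 1)$n_params,
                   as.integer(tally(dflt)))
  convonly <- uitrans_config(transformer_branch = FALSE, base_channels = 4L)
  expect_identical(build_uitrans(convonly, seed = 1)$n_params,
                   as.integer(tally(convonly)))
})

test_that("output shape equals input shape across configs and shapes", {
  configs <- list(
    tiny_config(),
    uitrans_config(n_stages = 2L, base_channels = 4L, transformer_branch = FALSE),
    uitrans_config(n_stages = 2L, base_channels = 4L, n_heads = 2L,
                   token_stride = 1L, conv_branch = FALSE),
    uitrans_config(n_stages = 1L, base_channels = 4L, n_heads = 2L,
                   token_stride = 2L))
  shapes <- list(c(8, 8, 8), c(8, 16, 16), c(16, 8, 16))
  for (cfg in configs) {
    m <- build_uitrans(cfg, seed = 1)
    for (sh in shapes) {
      x <- array(runif(prod(sh)), sh)
      y <- uitrans_restore(m, x)
      expect_identical(dim(y), as.integer(sh))
      expect_true(all(is.finite(y)))
    }
  }
})

test_that("three encoder stages reduce 64^3 to an 8^3 bottleneck", {
  m <- fixture("default_model", function() build_uitrans(uitrans_config(),
                                                         seed = 1))
  x <- array(runif(64^3), c(64, 64, 64))
  enc <- encoder_forward(x, m)
  expect_length(enc$skips, 3L)
  expect_identical(dim(enc$bottleneck)[1:3], c(8L, 8L, 8L))
  # channel bookkeeping: dual-branch width doubles the conv-only schedule
  expect_equal(dim(enc$bottleneck)[4], 2 * 16 * 2^3)
  sched <- m$schedule
  expect_equal(sched$width, c(64, 128, 256))
})

test_that("conv-only ablation has the documented bottleneck channel count", {
  cfg <- uitrans_config(base_channels = 4L, transformer_branch = FALSE)
  m <- build_uitrans(cfg, seed = 1)
  enc <- encoder_forward(array(runif(16^3), c(16, 16, 16)), m)
  expect_equal(dim(enc$bottleneck)[4], 4 * 2^3)
  # with the transformer branch disabled there are no attention parameters
  expect_false(any(vapply(m$params$enc, function(s) !is.null(s$tr), TRUE)))
})

test_that("indivisible or non-finite inputs are rejected with clear errors", {
  m <- build_uitrans(tiny_config(), seed = 1)
  expect_error(uitrans_restore(m, array(0, c(7, 8, 8))), "divisible by 4")
  bad <- array(0, c(8, 8, 8)); bad[1] <- NaN
  expect_error(uitrans_restore(m, bad), "finite")
  expect_error(uitrans_config(conv_branch = FALSE, transformer_branch = FALSE),
               "branch")
})

test_that("transformer block doubles channels; single MSA halves that", {
  x <- array(runif(8 * 8 * 8 * 16), c(8, 8, 8, 16))
  y <- transformer_block(x, n_heads = 4L, stride = 2L, seed = 2)
  expect_identical(dim(y), c(8L, 8L, 8L, 32L))
  y1 <- transformer_block(x, n_heads = 4L, stride = 2L, seed = 2, twin = FALSE)
  expect_identical(dim(y1)[4], 16L)
  expect_identical(dim(y1)[1:3], c(8L, 8L, 8L))
})

test_that("MSA preserves spatial size and normalizes attention rows", {
  x <- array(runif(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  y <- msa_module(x, n_heads = 4L, stride = 2L, seed = 5)
  expect_identical(dim(y), dim(x))
  A <- attr(y, "attention")
  for (Ah in A) {
    expect_true(all(abs(rowSums(Ah) - 1) < 1e-5))
    expect_true(all(Ah >= 0))
  }
  expect_error(msa_module(x, n_heads = 3L, stride = 2L), "divisible")
})

test_that("analytic gradients match finite differences through the full net", {
  cfg <- tiny_config()
  m <- build_uitrans(cfg, seed = 3)
  set.seed(42)
  x <- array(runif(8^3), c(8, 8, 8))
  tgt <- array(runif(8^3), c(8, 8, 8))
  lc <- loss_config(lambda_weight = 0.01, extractor_channels = c(4L, 6L, 6L))
  fw <- uitrans:::uitrans_fw(m, x, cache = TRUE)
  lg <- uitrans:::total_loss_grad(fw$y, tgt, lc)
  G <- uitrans:::uitrans_bw(m, fw$cache, lg$grad)

  loss_of <- function(mm) {
    y <- uitrans:::uitrans_fw(mm, x, cache = FALSE, apply_final = FALSE)
    uitrans:::total_loss_grad(y, tgt, lc)$loss
  }
  # a probe in every architectural component
  probes <- list(c("enc", 1L, "cv", "c1", "W"), c("enc", 1L, "tr", "m1", "Wq"),
                 c("enc", 2L, "tr", "m2", "Wp"), c("enc", 2L, "cv", "dn", "W"),
                 c("dec", 1L, "c2", "W"), c("head", "out", "W"),
                 c("enc", 1L, "tr", "m1", "ln1g"), c("enc", 2L, "tr", "m1", "W1"))
  eps <- 1e-5
  set.seed(9)
  pluck_path <- function(tree, pb) {
    for (k in pb)
      tree <- tree[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
    tree
  }
  for (pb in probes) {
    leaf <- pluck_path(m$params, pb)
    i <- sample(length(leaf), 1)
    perturb <- function(delta) {
      mm <- m
      path <- paste0(vapply(pb, function(k)
        if (grepl("^[0-9]+$", k)) sprintf("[[%s]]", k) else sprintf('[["%s"]]', k),
        ""), collapse = "")
      eval(parse(text = sprintf("mm$params%s[i] <- mm$params%s[i] + delta",
                                path, path)))
      mm
    }
    gnum <- (loss_of(perturb(eps)) - loss_of(perturb(-eps))) / (2 * eps)
    gana <- pluck_path(G, pb)
    expect_equal(gana[i], gnum, tolerance = 5e-3)
  }

  # residual connections keep gradients alive everywhere
  leaves <- uitrans:::tree_leaves(G)
  nz <- sum(vapply(leaves, function(g) sum(g != 0), 0))
  tot <- sum(vapply(leaves, length, 0))
  expect_gte(nz / tot, 0.99)
})
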