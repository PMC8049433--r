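# A deliberately small architecture so whole-model checks stay fast; the
# 32 = 2 * 2^4 length satisfies the pooling arithmetic.
tiny_config <- function(seed = 9L) {
  model_config(input_length = 32L, latent_dim = 2L,
               conv_channels = c(3L, 3L, 3L, 3L), conv_kernel = 3L,
               dense_widths_encoder = c(8L, 6L, 2L),
               dense_widths_decoder = c(6L, 8L, 10L, 32L), seed = seed)
}

test_that("the encoder emits 25-dim mean and log-variance, the decoder 400 samples", {
  m <- build_vae(model_config(seed = 1))
  x <- generate_cycle(cycle_spec())
  d <- vae_encode(m, x)
  expect_equal(dim(d$mean), c(1L, 25L))
  expect_equal(dim(d$logvar), c(1L, 25L))
  xhat <- vae_decode(m, d$mean)
  expect_equal(dim(xhat), c(1L, 400L))
})

test_that("shapes scale consistently for a 160 -> 10 -> 160 configuration", {
  m <- build_vae(model_config(input_length = 160L, latent_dim = 10L, seed = 2))
  X <- matrix(rnorm(3 * 160), 3, 160)
  d <- vae_encode(m, X)
  expect_equal(dim(d$mean), c(3L, 10L))
  expect_equal(dim(vae_decode(m, d$mean)), c(3L, 160L))
})

test_that("the pooling arithmetic is enforced at configuration time", {
  expect_error(model_config(input_length = 400L, latent_dim = 10L), "input_length")
  expect_error(model_config(input_length = 399L, latent_dim = 25L), "input_length")
  expect_error(model_config(conv_kernel = 4L), "conv_kernel")
})

test_that("encode/decode reject mismatched lengths by name", {
  m <- build_vae(tiny_config())
  expect_error(vae_encode(m, matrix(0, 2, 31)), "input_length")
  expect_error(vae_decode(m, matrix(0, 2, 3)), "latent_dim")
})

test_that("reparameterized sampling collapses to the mean in the zero-variance limit", {
  mu <- matrix(rnorm(25), 1, 25)
  z <- sample_latent(list(mean = mu, logvar = matrix(-50, 1, 25)), seed = 1)
  expect_lt(max(abs(z - mu)), 1e-10)
})

test_that("latent sampling is deterministic given a seed", {
  d <- list(mean = matrix(0, 1, 25), logvar = matrix(0, 1, 25))
  expect_identical(sample_latent(d, seed = 7), sample_latent(d, seed = 7))
})

test_that("latent draws match their nominal moments at n = 10,000", {
  d <- list(mean = matrix(0, 10000, 1), logvar = matrix(0, 10000, 1))
  z <- sample_latent(d, seed = 123)
  expect_lt(abs(mean(z)), 3 / sqrt(10000))
  expect_lt(abs(stats::var(z) - 1), 3 * sqrt(2 / 9999))
})

test_that("the closed-form KL matches hand values and the quadrature oracle", {
  expect_identical(kl_divergence(list(mean = rep(0, 25), logvar = rep(0, 25))), 0)
  expect_equal(kl_divergence(list(mean = 1, logvar = 0)), 0.5)
  set.seed(5)
  for (i in 1:10) {
    mu <- rnorm(1, 0, 2)
    lv <- rnorm(1, 0, 1)
    expect_equal(kl_divergence(list(mean = mu, logvar = lv)),
                 kl_1d_quadrature(mu, lv), tolerance = 1e-6)
  }
  expect_error(kl_divergence(list(mean = NaN, logvar = 0)), "finite")
})

test_that("KL is zero only at the prior and grows with the mean offset", {
  base <- kl_divergence(list(mean = 0.5, logvar = 0.2))
  expect_gt(base, 0)
  expect_gt(kl_divergence(list(mean = 1.0, logvar = 0.2)), base)
  expect_gt(kl_divergence(list(mean = -1.0, logvar = 0.2)), base)
})

test_that("reconstruction loss is the plain mean of squared differences", {
  x <- rnorm(400)
  expect_identical(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(rep(0, 400), rep(1, 400)), 1.0)
  set.seed(6)
  a <- rnorm(400); b <- rnorm(400)
  brute <- sum((a - b)^2) / 400
  expect_equal(reconstruction_loss(a, b), brute, tolerance = 1e-12)
  expect_error(reconstruction_loss(rnorm(400), rnorm(399)), "length")
})

test_that("compiled conv/pool/upsample layers match direct R oracles", {
  set.seed(13)
  l <- ecgvae:::nn_conv1d(3L, 4L, 5L)
  x <- array(rnorm(2 * 10 * 3), c(2, 10, 3))
  y <- ecgvae:::conv_forward(l, x, training = FALSE)
  Wa <- array(l$W, c(3, 5, 4))
  y_ref <- array(0, c(2, 10, 4))
  for (i in 1:2) for (t in 1:10) for (co in 1:4) {
    acc <- l$b[co]
    for (j in 1:5) {
      tt <- t + j - 3  # pad = 2
      if (tt >= 1 && tt <= 10) for (ci in 1:3) acc <- acc + x[i, tt, ci] * Wa[ci, j, co]
    }
    y_ref[i, t, co] <- acc
  }
  expect_equal(y, y_ref, tolerance = 1e-12)

  p <- ecgvae:::nn_maxpool(2L)
  xp <- array(rnorm(3 * 8 * 2), c(3, 8, 2))
  yp <- ecgvae:::maxpool_forward(p, xp, training = FALSE)
  yp_ref <- pmax(xp[, seq(1, 8, 2), , drop = FALSE], xp[, seq(2, 8, 2), , drop = FALSE])
  expect_equal(yp, yp_ref, tolerance = 1e-15)

  u <- ecgvae:::nn_upsample(2L)
  yu <- ecgvae:::upsample_forward(u, xp, training = FALSE)
  expect_equal(yu[, seq(1, 16, 2), , drop = FALSE], xp, tolerance = 1e-15)
  expect_equal(yu[, seq(2, 16, 2), , drop = FALSE], xp, tolerance = 1e-15)
})

test_that("compiled batch norm matches the textbook R formulas", {
  set.seed(14)
  l <- ecgvae:::nn_batchnorm(4L)
  x <- matrix(rnorm(20, sd = 3), 5, 4)
  y <- ecgvae:::bn_forward(l, x, training = TRUE)
  mu <- colMeans(x)
  v <- colMeans(sweep(x, 2, mu)^2)
  y_ref <- sweep(sweep(x, 2, mu), 2, sqrt(v + l$eps), "/")
  expect_equal(y, y_ref, tolerance = 1e-12)  # gamma = 1, beta = 0 at init
  # inference mode uses the running statistics
  y_inf <- ecgvae:::bn_forward(l, x, training = FALSE)
  y_inf_ref <- sweep(sweep(x, 2, l$run_mean), 2, sqrt(l$run_var + l$eps), "/")
  expect_equal(y_inf, y_inf_ref, tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  m <- build_vae(tiny_config())
  set.seed(21)
  X <- matrix(rnorm(5 * 32), 5, 32)
  eps_fix <- matrix(rnorm(5 * 2), 5, 2)
  L <- 32L; n_b <- 5L; beta <- 1.0
  loss_fn <- function() {
    d <- vae_encode(m, X, training = TRUE)
    z <- d$mean + exp(d$logvar / 2) * eps_fix
    xhat <- vae_decode(m, z, training = TRUE)
    mean((xhat - X)^2) +
      beta * 0.5 * mean(rowSums(d$mean^2 + exp(d$logvar) - d$logvar - 1)) / L
  }
  d <- vae_encode(m, X, training = TRUE)
  sd_ <- exp(d$logvar / 2)
  xhat <- vae_decode(m, d$mean + sd_ * eps_fix, training = TRUE)
  dz <- ecgvae:::vae_decode_backward(m, 2 * (xhat - X) / (n_b * L))
  ecgvae:::vae_encode_backward(
    m, dz + beta * d$mean / (L * n_b),
    dz * eps_fix * 0.5 * sd_ + beta * 0.5 * (exp(d$logvar) - 1) / (L * n_b))
  layers <- ecgvae:::vae_layers(m)
  for (l in layers) if (l$type == "batchnorm") l$momentum <- 1  # freeze stats
  set.seed(22)
  for (l in layers) {
    for (p in l$param_names) {
      g <- l[[paste0("d", p)]]
      for (i in sample(length(l[[p]]), min(2L, length(l[[p]])))) {
        h <- 1e-5
        orig <- l[[p]][i]
        l[[p]][i] <- orig + h; fp <- loss_fn()
        l[[p]][i] <- orig - h; fm <- loss_fn()
        l[[p]][i] <- orig
        num <- (fp - fm) / (2 * h)
        if (abs(num) + abs(g[i]) > 1e-8) {
          expect_lt(abs(num - g[i]) / (abs(num) + abs(g[i])), 1e-4)
        }
      }
    }
  }
})

test_that("the autoencoding round trip preserves length for any valid config", {
  for (cfg in list(tiny_config(), model_config(input_length = 160L, latent_dim = 10L,
                                               seed = 3))) {
    m <- build_vae(cfg)
    X <- matrix(rnorm(4 * cfg$input_length), 4, cfg$input_length)
    z <- sample_latent(vae_encode(m, X), seed = 1)
    expect_equal(dim(vae_decode(m, z)), dim(X))
  }
})

test_that("encode and decode are deterministic in inference mode", {
  m <- build_vae(tiny_config())
  X <- matrix(rnorm(3 * 32), 3, 32)
  expect_identical(vae_encode(m, X)$mean, vae_encode(m, X)$mean)
  Z <- matrix(rnorm(3 * 2), 3, 2)
  expect_identical(vae_decode(m, Z), vae_decode(m, Z))
})

test_that("combined-loss gradients are finite everywhere on a random batch", {
  m <- build_vae(tiny_config(seed = 31))
  set.seed(32)
  X <- matrix(rnorm(8 * 32), 8, 32)
  opt <- ecgvae:::adam_state(ecgvae:::vae_layers(m))
  losses <- ecgvae:::vae_train_step(m, X, beta = 1.0, opt)
  expect_true(all(vapply(losses, is.finite, logical(1))))
  for (l in ecgvae:::vae_layers(m)) {
    for (p in l$param_names) {
      expect_true(all(is.finite(l[[paste0("d", p)]])))
    }
  }
})
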