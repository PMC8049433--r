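# Shared fixtures: everything is generated in code, nothing is read from
# disk. The benchmark model is trained lazily once per test run and cached,
# so only the files that need a trained model pay for it.

.fixture_cache <- new.env(parent = emptyenv())

# Study-condition simulator settings used across files: default morphology,
# 5% relative jitter, 0.02 mV additive noise.
bench_spec <- function() cycle_spec(noise_sd = 0.02)

# The desk-scale trained model used by interface-level tests (traversal,
# feature extraction, generation envelope): 2,000 cycles, 50 epochs — the
# same conditions as the acceptance suite. The acceptance file seeds this
# cache when it runs first (alphabetical order), so the model is trained
# at most once per test run.
get_benchmark_model <- function() {
  if (is.null(.fixture_cache$benchmark)) {
    train <- generate_dataset(bench_spec(), 2000, jitter = 0.05, seed = 101)
    fit <- vae_train(train, model_config(seed = 11),
                     training_config(epochs = 50, batch_size = 64, seed = 12))
    .fixture_cache$benchmark <- list(fit = fit, train = train)
  }
  .fixture_cache$benchmark
}

set_benchmark_model <- function(fit, train) {
  .fixture_cache$benchmark <- list(fit = fit, train = train)
}

# Independent O(n^2) double-loop oracle for the squared MMD with an
# explicit Gaussian kernel; deliberately naive.
mmd_bruteforce <- function(X, Y, sigma, estimator) {
  kern <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  n <- nrow(X); m <- nrow(Y)
  sxx <- 0; for (i in 1:n) for (j in 1:n) sxx <- sxx + kern(X[i, ], X[j, ])
  syy <- 0; for (i in 1:m) for (j in 1:m) syy <- syy + kern(Y[i, ], Y[j, ])
  sxy <- 0; for (i in 1:n) for (j in 1:m) sxy <- sxy + kern(X[i, ], Y[j, ])
  if (estimator == "biased") {
    sxx / n^2 + syy / m^2 - 2 * sxy / (n * m)
  } else {
    dxx <- 0; for (i in 1:n) dxx <- dxx + kern(X[i, ], X[i, ])
    dyy <- 0; for (i in 1:m) dyy <- dyy + kern(Y[i, ], Y[i, ])
    (sxx - dxx) / (n * (n - 1)) + (syy - dyy) / (m * (m - 1)) - 2 * sxy / (n * m)
  }
}

# 1-D KL(P || N(0,1)) for P = N(mu, sigma^2) by numerical integration of
# the defining integral of p*log(p/q); log densities keep the integrand
# finite where q underflows.
kl_1d_quadrature <- function(mu, logvar) {
  s <- exp(logvar / 2)
  f <- function(x) {
    lp <- stats::dnorm(x, mu, s, log = TRUE)
    lq <- stats::dnorm(x, 0, 1, log = TRUE)
    exp(lp) * (lp - lq)
  }
  stats::integrate(f, mu - 12 * s, mu + 12 * s,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Expectation of a jittered single-Gaussian wave at times t_ms under the
# simulator's multiplicative perturbation model. Amplitude enters linearly
# (E[a(1+e)] = a). The center integral is exact: averaging
# exp(-(t - c(1+e))^2 / (2 w^2)) over e ~ N(0,1) is a Gaussian-Gaussian
# convolution,
#   w / sqrt(w^2 + (c j)^2) * exp(-(t - c)^2 / (2 (w^2 + (c j)^2))).
# Only the width perturbation needs quadrature (1-D, with the same 0.05
# clamp the simulator applies).
jittered_wave_expectation <- function(amplitude, center, width, jitter, t_ms,
                                      n_grid = 2001) {
  e <- seq(-8, 8, length.out = n_grid)
  wgt <- stats::dnorm(e)
  wgt <- wgt / sum(wgt)
  cj2 <- (center * jitter)^2
  acc <- numeric(length(t_ms))
  for (j in seq_along(e)) {
    w <- width * max(1 + jitter * e[j], 0.05)
    s2 <- w^2 + cj2
    acc <- acc + wgt[j] * (w / sqrt(s2)) * exp(-(t_ms - center)^2 / (2 * s2))
  }
  amplitude * acc
}
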