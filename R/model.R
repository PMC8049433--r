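#' VAE architecture configuration
#'
#' The encoder maps a length-`input_length` cycle through two parallel
#' branches — a convolutional chain of four conv / batch-norm / ReLU /
#' max-pool blocks plus one final convolution collapsing to a single
#' channel, and a dense chain of three dense / batch-norm / ReLU blocks —
#' each ending in `latent_dim` values. The two branch outputs are
#' concatenated (length `2 * latent_dim`) and two independent dense heads
#' produce the latent mean and log-variance vectors. The decoder mirrors
#' this: a dense chain of four dense / batch-norm / ReLU blocks to
#' `input_length` values and a deconvolution chain (conv / batch-norm /
#' ReLU / x2 upsample, four blocks) from the latent vector reshaped to
#' `latent_dim` positions, concatenated to `2 * input_length` values and
#' reduced by one final dense layer to the reconstructed cycle.
#'
#' The pooling/upsampling arithmetic requires
#' `input_length == latent_dim * pool_factor^4` (400 = 25 * 2^4 at the
#' defaults), which makes the convolutional branch emit exactly
#' `latent_dim` values with "same" padding.
#'
#' @param input_length Samples per cycle (default 400).
#' @param latent_dim Number of latent features (default 25).
#' @param conv_channels Channel counts of the four encoder conv blocks;
#'   the decoder deconvolution chain uses the mirrored counts ending in a
#'   single channel.
#' @param conv_kernel Odd convolution kernel width in samples (default 7).
#' @param dense_widths_encoder Widths of the three encoder dense layers;
#'   the last must equal `latent_dim` (default `c(256, 64, latent_dim)`).
#' @param dense_widths_decoder Widths of the four decoder dense layers;
#'   the last must equal `input_length` (default
#'   `c(64, 128, 256, input_length)`).
#' @param pool_factor Max-pool / upsample factor per block (default 2).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_length = 400L, latent_dim = 25L,
                         conv_channels = c(8L, 16L, 32L, 64L),
                         conv_kernel = 7L,
                         dense_widths_encoder = NULL,
                         dense_widths_decoder = NULL,
                         pool_factor = 2L, seed = 42L) {
  check_that(is.numeric(latent_dim) && length(latent_dim) == 1L && latent_dim >= 1,
             "latent_dim", "must be at least 1")
  check_that(is.numeric(pool_factor) && length(pool_factor) == 1L && pool_factor >= 1,
             "pool_factor", "must be at least 1")
  shrink <- as.integer(pool_factor)^4
  check_that(input_length %% shrink == 0, "input_length",
             sprintf("%d is not divisible by pool_factor^4 = %d", input_length, shrink))
  check_that(input_length == latent_dim * shrink, "input_length",
             sprintf("must equal latent_dim * pool_factor^4 (%d * %d = %d, got %d)",
                     as.integer(latent_dim), shrink,
                     as.integer(latent_dim) * shrink, as.integer(input_length)))
  check_that(length(conv_channels) == 4, "conv_channels", "must list 4 channel counts")
  check_that(conv_kernel %% 2 == 1 && conv_kernel >= 1, "conv_kernel", "must be odd and >= 1")
  if (is.null(dense_widths_encoder)) dense_widths_encoder <- c(256L, 64L, latent_dim)
  if (is.null(dense_widths_decoder)) dense_widths_decoder <- c(64L, 128L, 256L, input_length)
  check_that(length(dense_widths_encoder) == 3, "dense_widths_encoder", "must list 3 widths")
  check_that(dense_widths_encoder[3] == latent_dim, "dense_widths_encoder",
             sprintf("last width must equal latent_dim (%d)", as.integer(latent_dim)))
  check_that(length(dense_widths_decoder) == 4, "dense_widths_decoder", "must list 4 widths")
  check_that(dense_widths_decoder[4] == input_length, "dense_widths_decoder",
             sprintf("last width must equal input_length (%d)", as.integer(input_length)))
  structure(list(input_length = as.integer(input_length),
                 latent_dim = as.integer(latent_dim),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 dense_widths_encoder = as.integer(dense_widths_encoder),
                 dense_widths_decoder = as.integer(dense_widths_decoder),
                 pool_factor = as.integer(pool_factor),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) VAE
#'
#' Instantiates all layers of the architecture described in
#' [model_config()] with He-normal initial weights drawn under
#' `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `vae_model`.
#' @export
build_vae <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  k <- config$conv_kernel
  ch <- config$conv_channels
  dw_e <- config$dense_widths_encoder
  dw_d <- config$dense_widths_decoder
  L <- config$input_length
  Z <- config$latent_dim
  pf <- config$pool_factor
  dec_ch <- c(rev(ch)[-1], 1L)  # e.g. (8,16,32,64) -> (32,16,8,1)
  m <- with_seed(config$seed, {
    enc_conv <- list()
    prev <- 1L
    for (c_out in ch) {
      enc_conv <- c(enc_conv, list(nn_conv1d(prev, c_out, k),
                                   nn_batchnorm(c_out, spatial = TRUE),
                                   nn_relu(), nn_maxpool(pf)))
      prev <- c_out
    }
    enc_conv <- c(enc_conv, list(nn_conv1d(prev, 1L, k)))  # final conv, linear
    enc_dense <- list()
    prev <- L
    for (w in dw_e) {
      enc_dense <- c(enc_dense, list(nn_dense(prev, w), nn_batchnorm(w), nn_relu()))
      prev <- w
    }
    head_mean <- nn_dense(2L * Z, Z)
    head_logvar <- nn_dense(2L * Z, Z)
    dec_dense <- list()
    prev <- Z
    for (w in dw_d) {
      dec_dense <- c(dec_dense, list(nn_dense(prev, w), nn_batchnorm(w), nn_relu()))
      prev <- w
    }
    dec_conv <- list()
    prev <- 1L
    for (c_out in dec_ch) {
      dec_conv <- c(dec_conv, list(nn_conv1d(prev, c_out, k),
                                   nn_batchnorm(c_out, spatial = TRUE),
                                   nn_relu(), nn_upsample(pf)))
      prev <- c_out
    }
    out_dense <- nn_dense(2L * L, L)
    list(config = config,
         enc_conv = enc_conv, enc_dense = enc_dense,
         head_mean = head_mean, head_logvar = head_logvar,
         dec_dense = dec_dense, dec_conv = dec_conv,
         out_dense = out_dense)
  })
  class(m) <- "vae_model"
  m
}

#' @export
print.vae_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(vae_layers(x), function(l) {
    sum(vapply(l$param_names, function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
  cat(sprintf("<vae_model> %d -> %d -> %d (dual-branch 1-D conv VAE, %s parameters)\n",
              cfg$input_length, cfg$latent_dim, cfg$input_length,
              format(n_par, big.mark = ",")))
  invisible(x)
}

vae_layers <- function(model) {
  c(model$enc_conv, model$enc_dense,
    list(model$head_mean, model$head_logvar),
    model$dec_dense, model$dec_conv, list(model$out_dense))
}

#' Encode cycles to latent distributions
#'
#' Runs the encoder on a batch of cycles and returns the per-cycle latent
#' mean and log-variance matrices. With batch normalization in inference
#' mode (`training = FALSE`, the default) this is a deterministic function.
#'
#' @param model A [build_vae()] model.
#' @param x Numeric batch matrix (n x `input_length`) or a single cycle
#'   vector.
#' @param training Use batch statistics and cache activations for
#'   backpropagation (internal; leave `FALSE` for feature extraction).
#' @return A list of class `latent_distribution` with `mean` and `logvar`
#'   (each n x `latent_dim`).
#' @export
vae_encode <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "vae_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  L <- model$config$input_length
  check_that(ncol(x) == L, "x",
             sprintf("cycle length %d does not match model input_length %d", ncol(x), L))
  n <- nrow(x)
  if (!training && n > 512L) {
    # inference is row-independent; chunk large batches to bound the im2col
    # working memory
    parts <- lapply(split(seq_len(n), ceiling(seq_len(n) / 512L)), function(idx) {
      vae_encode(model, x[idx, , drop = FALSE], training = FALSE)
    })
    return(structure(list(mean = do.call(rbind, lapply(parts, `[[`, "mean")),
                          logvar = do.call(rbind, lapply(parts, `[[`, "logvar"))),
                     class = "latent_distribution"))
  }
  a <- array(x, c(n, L, 1L))
  hc <- chain_forward(model$enc_conv, a, training)
  dim(hc) <- c(n, model$config$latent_dim)
  hd <- chain_forward(model$enc_dense, x, training)
  h <- cbind(hc, hd)
  mean <- dense_forward(model$head_mean, h, training)
  logvar <- dense_forward(model$head_logvar, h, training)
  structure(list(mean = mean, logvar = logvar), class = "latent_distribution")
}

# Backward pass of the encoder; call only after vae_encode(training = TRUE).
vae_encode_backward <- function(model, dmean, dlogvar) {
  dh <- dense_backward(model$head_mean, dmean) +
    dense_backward(model$head_logvar, dlogvar)
  Z <- model$config$latent_dim
  n <- nrow(dh)
  dhc <- dh[, seq_len(Z), drop = FALSE]
  dhd <- dh[, Z + seq_len(Z), drop = FALSE]
  da <- chain_backward(model$enc_conv, array(dhc, c(n, Z, 1L)))
  dx_dense <- chain_backward(model$enc_dense, dhd)
  dx <- dx_dense
  dim(da) <- dim(dx)
  dx + da
}

#' Decode latent vectors to cycles
#'
#' Runs the decoder on a batch of latent vectors. Deterministic in
#' inference mode.
#'
#' @param model A [build_vae()] model.
#' @param z Numeric batch matrix (n x `latent_dim`) or a single latent
#'   vector.
#' @param training Internal; see [vae_encode()].
#' @return Numeric matrix (n x `input_length`) of reconstructed cycles (mV).
#' @export
vae_decode <- function(model, z, training = FALSE) {
  stopifnot(inherits(model, "vae_model"))
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  Z <- model$config$latent_dim
  check_that(ncol(z) == Z, "z",
             sprintf("latent length %d does not match model latent_dim %d", ncol(z), Z))
  n <- nrow(z)
  if (!training && n > 512L) {
    parts <- lapply(split(seq_len(n), ceiling(seq_len(n) / 512L)), function(idx) {
      vae_decode(model, z[idx, , drop = FALSE], training = FALSE)
    })
    return(do.call(rbind, parts))
  }
  hd <- chain_forward(model$dec_dense, z, training)
  hc <- chain_forward(model$dec_conv, array(z, c(n, Z, 1L)), training)
  dim(hc) <- c(n, model$config$input_length)
  h <- cbind(hc, hd)
  dense_forward(model$out_dense, h, training)
}

# Backward pass of the decoder; returns the gradient w.r.t. z.
vae_decode_backward <- function(model, dxhat) {
  dh <- dense_backward(model$out_dense, dxhat)
  L <- model$config$input_length
  Z <- model$config$latent_dim
  n <- nrow(dh)
  dhc <- dh[, seq_len(L), drop = FALSE]
  dhd <- dh[, L + seq_len(L), drop = FALSE]
  dz_conv <- chain_backward(model$dec_conv, array(dhc, c(n, L, 1L)))
  dim(dz_conv) <- c(n, Z)
  dz_dense <- chain_backward(model$dec_dense, dhd)
  dz_conv + dz_dense
}

#' Sample latent vectors by reparameterization
#'
#' Draws `z = mean + exp(logvar / 2) * eps` with `eps ~ N(0, I)`, the
#' reparameterization that keeps sampling differentiable with respect to
#' the distribution parameters. Deterministic given `seed`.
#'
#' @param dist A `latent_distribution` (from [vae_encode()]) or a list with
#'   `mean` and `logvar` matrices/vectors.
#' @param seed Optional integer seed.
#' @return Numeric matrix of latent draws, same shape as `dist$mean`.
#' @export
sample_latent <- function(dist, seed = NULL) {
  mean <- dist$mean
  logvar <- dist$logvar
  if (is.vector(mean)) mean <- matrix(mean, nrow = 1)
  if (is.vector(logvar)) logvar <- matrix(logvar, nrow = 1)
  check_that(all(dim(mean) == dim(logvar)), "dist", "mean and logvar shapes differ")
  check_that(all(is.finite(logvar)), "logvar", "must be finite")
  eps <- with_seed(seed, matrix(rnorm(length(mean)), nrow(mean), ncol(mean)))
  mean + exp(logvar / 2) * eps
}

#' Kullback-Leibler divergence to the standard-normal prior
#'
#' Closed form for a diagonal Gaussian `N(mean, diag(exp(logvar)))` against
#' `N(0, I)`: `0.5 * sum(mean^2 + exp(logvar) - logvar - 1)` nats. For a
#' batch (matrix input) the per-row divergences are averaged.
#'
#' @param dist A `latent_distribution` or list with `mean` and `logvar`.
#' @return Nonnegative scalar (nats).
#' @export
kl_divergence <- function(dist) {
  mean <- dist$mean
  logvar <- dist$logvar
  if (is.vector(mean)) mean <- matrix(mean, nrow = 1)
  if (is.vector(logvar)) logvar <- matrix(logvar, nrow = 1)
  check_that(all(is.finite(mean)) && all(is.finite(logvar)), "dist",
             "mean and logvar must be finite")
  per_row <- 0.5 * rowSums(mean^2 + exp(logvar) - logvar - 1)
  mean(per_row)
}

#' Mean squared reconstruction error
#'
#' @param x,xhat Numeric vectors or matrices of equal shape (mV).
#' @return Scalar mean of squared differences (mV^2).
#' @export
reconstruction_loss <- function(x, xhat) {
  check_that(length(x) == length(xhat), "x",
             sprintf("length %d does not match xhat length %d", length(x), length(xhat)))
  mean((x - xhat)^2)
}
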