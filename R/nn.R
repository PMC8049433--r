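# Minimal neural-network layer kit used by the VAE: dense, 1-D convolution
# ("same" padding, via im2col), batch normalization, ReLU, max-pooling and
# nearest-neighbour upsampling, each with an analytic backward pass, plus an
# Adam optimizer. Layers are environments so that parameter updates mutate
# in place; the analytic gradients are verified against central finite
# differences in the test suite.
#
# Tensor conventions: dense layers operate on (batch x features) matrices;
# convolutional layers on (batch x length x channels) arrays. Batch norm
# normalizes per feature (dense) or per channel pooling batch and length
# (conv).

# Add/multiply a row vector into every row of an (m x n) matrix without
# materializing a broadcast matrix: rep(each = m) lines up with column-major
# storage.
add_row <- function(x, v) x + rep(v, each = nrow(x))
mul_row <- function(x, v) x * rep(v, each = nrow(x))

nn_dense <- function(n_in, n_out) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"
  l$W <- matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
  l$b <- numeric(n_out)
  l$param_names <- c("W", "b")
  l
}

dense_forward <- function(l, x, training) {
  if (training) l$x <- x
  add_row(x %*% l$W, l$b)
}

dense_backward <- function(l, dy) {
  l$dW <- crossprod(l$x, dy)
  l$db <- colSums(dy)
  dy %*% t(l$W)
}

nn_relu <- function() {
  l <- new.env(parent = emptyenv())
  l$type <- "relu"
  l$param_names <- character(0)
  l
}

relu_forward <- function(l, x, training) {
  y <- relu_fwd(x)
  if (training) l$y <- y
  y
}

relu_backward <- function(l, dy) relu_bwd(dy, l$y)

# Batch normalization over the columns of a (m x n) matrix. For conv inputs
# the (batch x length x channels) array is flattened to (batch*length x
# channels) first, so statistics pool batch and length per channel.
nn_batchnorm <- function(n, spatial = FALSE, momentum = 0.9, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "batchnorm"
  l$spatial <- spatial
  l$gamma <- rep(1, n)
  l$beta <- rep(0, n)
  l$run_mean <- rep(0, n)
  l$run_var <- rep(1, n)
  l$momentum <- momentum
  l$eps <- eps
  l$param_names <- c("gamma", "beta")
  l
}

bn_forward <- function(l, x, training) {
  dims <- dim(x)
  if (l$spatial) dim(x) <- c(dims[1] * dims[2], dims[3])
  if (training) {
    out <- bn_train_fwd(x, l$gamma, l$beta, l$eps)
    l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * out$mu
    l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * out$var
    l$xhat <- out$xhat
    l$invstd <- out$invstd
    y <- out$y
    if (l$spatial) dim(y) <- dims
    return(y)
  }
  scale <- l$gamma / sqrt(l$run_var + l$eps)
  y <- add_row(mul_row(x, scale), l$beta - l$run_mean * scale)
  if (l$spatial) dim(y) <- dims
  y
}

bn_backward <- function(l, dy) {
  dims <- dim(dy)
  if (l$spatial) dim(dy) <- c(dims[1] * dims[2], dims[3])
  out <- bn_train_bwd(dy, l$xhat, l$gamma, l$invstd)
  l$dgamma <- out$dgamma
  l$dbeta <- out$dbeta
  dx <- out$dx
  if (l$spatial) dim(dx) <- dims
  dx
}

# 1-D convolution with "same" zero padding (odd kernel), stride 1, so that
# pooling alone controls the sequence length.
nn_conv1d <- function(in_ch, out_ch, kernel) {
  stopifnot(kernel %% 2 == 1)
  l <- new.env(parent = emptyenv())
  l$type <- "conv1d"
  l$kernel <- as.integer(kernel)
  l$in_ch <- as.integer(in_ch)
  l$out_ch <- as.integer(out_ch)
  l$W <- matrix(rnorm(kernel * in_ch * out_ch, 0, sqrt(2 / (kernel * in_ch))),
                kernel * in_ch, out_ch)
  l$b <- numeric(out_ch)
  l$param_names <- c("W", "b")
  l
}

conv_forward <- function(l, x, training) {
  d <- dim(x)
  if (training) {
    l$x <- x
    l$in_dim <- d
  }
  conv1d_fwd(x, l$W, l$b, d[1], d[2], d[3], l$kernel, l$out_ch)
}

conv_backward <- function(l, dy) {
  d <- l$in_dim
  n <- d[1]; L <- d[2]; C <- d[3]
  l$dW <- conv1d_bwd_filter(l$x, dy, n, L, C, l$kernel, l$out_ch)
  dy2 <- dy
  dim(dy2) <- c(n * L, l$out_ch)
  l$db <- colSums(dy2)
  conv1d_bwd_data(dy, l$W, n, L, C, l$kernel, l$out_ch)
}

nn_maxpool <- function(factor = 2L) {
  l <- new.env(parent = emptyenv())
  l$type <- "maxpool"
  l$factor <- as.integer(factor)
  l$param_names <- character(0)
  l
}

maxpool_forward <- function(l, x, training) {
  d <- dim(x)
  stopifnot(d[2] %% l$factor == 0)
  out <- maxpool_fwd(x, d[1], d[2], d[3], l$factor)
  if (training) {
    l$arg <- out$arg
    l$in_dim <- d
  }
  out$y
}

maxpool_backward <- function(l, dy) {
  d <- l$in_dim
  maxpool_bwd(dy, l$arg, d[1], d[2], d[3], l$factor)
}

nn_upsample <- function(factor = 2L) {
  l <- new.env(parent = emptyenv())
  l$type <- "upsample"
  l$factor <- as.integer(factor)
  l$param_names <- character(0)
  l
}

upsample_forward <- function(l, x, training) {
  d <- dim(x)
  if (training) l$in_dim <- d
  upsample_fwd(x, d[1], d[2], d[3], l$factor)
}

upsample_backward <- function(l, dy) {
  d <- l$in_dim
  upsample_bwd(dy, d[1], d[2], d[3], l$factor)
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    dense = dense_forward(l, x, training),
    relu = relu_forward(l, x, training),
    batchnorm = bn_forward(l, x, training),
    conv1d = conv_forward(l, x, training),
    maxpool = maxpool_forward(l, x, training),
    upsample = upsample_forward(l, x, training),
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    dense = dense_backward(l, dy),
    relu = relu_backward(l, dy),
    batchnorm = bn_backward(l, dy),
    conv1d = conv_backward(l, dy),
    maxpool = maxpool_backward(l, dy),
    upsample = upsample_backward(l, dy),
    stop("unknown layer type: ", l$type)
  )
}

chain_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

chain_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(layers, learning_rate = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$layers <- layers
  st$lr <- learning_rate
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st$t <- 0L
  for (l in layers) {
    for (p in l$param_names) {
      l[[paste0("adam_m_", p)]] <- l[[p]] * 0
      l[[paste0("adam_v_", p)]] <- l[[p]] * 0
    }
  }
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  c1 <- 1 - st$beta1^st$t
  c2 <- 1 - st$beta2^st$t
  for (l in st$layers) {
    for (p in l$param_names) {
      g <- l[[paste0("d", p)]]
      mkey <- paste0("adam_m_", p)
      vkey <- paste0("adam_v_", p)
      m <- st$beta1 * l[[mkey]] + (1 - st$beta1) * g
      v <- st$beta2 * l[[vkey]] + (1 - st$beta2) * g * g
      l[[mkey]] <- m
      l[[vkey]] <- v
      l[[p]] <- l[[p]] - st$lr * (m / c1) / (sqrt(v / c2) + st$eps)
    }
  }
  invisible(st)
}
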