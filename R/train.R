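#' Training configuration
#'
#' The optimizer (Adam) and the 720-epoch default follow the method's
#' training protocol; batch size, learning rate and the KL weight are
#' package conventions surfaced here because the protocol leaves them open.
#'
#' @param epochs Number of passes over the training rows (default 720).
#' @param batch_size Rows per Adam step (default 64).
#' @param learning_rate Adam step size (default 1e-2, chosen by pilot runs
#'   on the synthetic benchmark; see the methods vignette).
#' @param kl_weight Nonnegative weight `beta` on the KL term. The
#'   per-sample objective is `MSE + beta * KL / input_length`; at the
#'   default `beta = 1` this equals the plain unweighted objective (sum of
#'   squared errors plus KL) divided by the constant cycle length, so the
#'   two loss components stay on comparable scales for any batch size.
#'   `beta = 0` trains a plain autoencoder.
#' @param kl_warmup_epochs Linearly ramp `beta` from 0 over this many
#'   initial epochs (0 disables warm-up, the default).
#' @param seed Integer seed controlling shuffling, the validation split and
#'   the reparameterization draws.
#' @param checkpoint_every Write a checkpoint every this many epochs into
#'   `checkpoint_dir` (0 disables periodic checkpoints).
#' @param validation_fraction Fraction of rows held out for per-epoch
#'   validation losses, in \[0, 1).
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 720L, batch_size = 64L,
                            learning_rate = 1e-2, kl_weight = 1.0,
                            kl_warmup_epochs = 0L, seed = 1L,
                            checkpoint_every = 0L,
                            validation_fraction = 0) {
  check_that(is.numeric(epochs) && length(epochs) == 1L && epochs >= 1,
             "epochs", "must be at least 1")
  check_that(is.numeric(batch_size) && length(batch_size) == 1L && batch_size >= 1,
             "batch_size", "must be at least 1")
  check_that(is.numeric(learning_rate) && length(learning_rate) == 1L && learning_rate > 0,
             "learning_rate", "must be positive")
  check_that(is.numeric(kl_weight) && length(kl_weight) == 1L && kl_weight >= 0,
             "kl_weight", "must be nonnegative")
  check_that(is.numeric(validation_fraction) && length(validation_fraction) == 1L &&
               validation_fraction >= 0 && validation_fraction < 1,
             "validation_fraction", "must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, kl_weight = kl_weight,
                 kl_warmup_epochs = as.integer(kl_warmup_epochs),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 validation_fraction = validation_fraction),
            class = "training_config")
}

# One forward/backward/update step on a batch; returns the loss components.
vae_train_step <- function(model, X, beta, opt) {
  L <- model$config$input_length
  n_b <- nrow(X)
  dist <- vae_encode(model, X, training = TRUE)
  eps <- matrix(rnorm(length(dist$mean)), n_b, model$config$latent_dim)
  sd_ <- exp(dist$logvar / 2)
  z <- dist$mean + sd_ * eps
  xhat <- vae_decode(model, z, training = TRUE)
  recon <- mean((xhat - X)^2)
  kl <- 0.5 * mean(rowSums(dist$mean^2 + exp(dist$logvar) - dist$logvar - 1))
  total <- recon + beta * kl / L
  # gradients of the batch objective
  dxhat <- 2 * (xhat - X) / (n_b * L)
  dz <- vae_decode_backward(model, dxhat)
  dmean <- dz + (beta / (L * n_b)) * dist$mean
  dlogvar <- dz * eps * 0.5 * sd_ +
    (beta / (L * n_b)) * 0.5 * (exp(dist$logvar) - 1)
  vae_encode_backward(model, dmean, dlogvar)
  adam_step(opt)
  list(recon = recon, kl = kl, total = total)
}

# Loss components without updating parameters (inference-mode batch norm).
vae_eval_loss <- function(model, X, beta) {
  L <- model$config$input_length
  dist <- vae_encode(model, X, training = FALSE)
  eps <- matrix(rnorm(length(dist$mean)), nrow(X), model$config$latent_dim)
  z <- dist$mean + exp(dist$logvar / 2) * eps
  xhat <- vae_decode(model, z, training = FALSE)
  recon <- mean((xhat - X)^2)
  kl <- 0.5 * mean(rowSums(dist$mean^2 + exp(dist$logvar) - dist$logvar - 1))
  list(recon = recon, kl = kl, total = recon + beta * kl / L)
}

#' Train the VAE on a cycle matrix
#'
#' Minimizes the per-sample objective `MSE + beta * KL / input_length`
#' (see [training_config()]) with Adam over shuffled mini-batches. No data
#' augmentation is performed. All randomness — weight initialization (via
#' `model_config$seed`), the validation split, shuffling, and the
#' reparameterization draws — is controlled by the two seeds, so a rerun
#' with identical configs reproduces the history bit-for-bit.
#'
#' @param data A [cycle_matrix()] or numeric matrix with at least
#'   `batch_size` rows and row length `input_length`.
#' @param model_config A [model_config()].
#' @param train_config A [training_config()].
#' @param checkpoint_dir Directory for periodic checkpoints when
#'   `checkpoint_every > 0`.
#' @param verbose Print a one-line summary every 10 epochs.
#' @return A list of class `vae_fit` with `model` (the trained
#'   [build_vae()] model) and `history` (a data frame with one row per
#'   epoch: reconstruction, KL and total loss on the training split, plus
#'   validation columns when a split is configured).
#' @export
vae_train <- function(data, model_config = NULL, train_config = training_config(),
                      checkpoint_dir = NULL, verbose = FALSE) {
  X <- as_cycle_values(data, "data")
  if (is.null(model_config)) {
    model_config <- ecgvae::model_config(input_length = ncol(X),
                                         latent_dim = ncol(X) %/% 16L)
  }
  stopifnot(inherits(model_config, "model_config"),
            inherits(train_config, "training_config"))
  check_that(ncol(X) == model_config$input_length, "data",
             sprintf("cycle length %d does not match model input_length %d",
                     ncol(X), model_config$input_length))
  check_that(nrow(X) >= train_config$batch_size, "data",
             sprintf("%d row(s) is fewer than batch_size %d",
                     nrow(X), train_config$batch_size))
  model <- build_vae(model_config)
  opt <- adam_state(vae_layers(model), learning_rate = train_config$learning_rate)
  epochs <- train_config$epochs
  hist_cols <- c("epoch", "recon", "kl", "total")
  has_val <- train_config$validation_fraction > 0
  history <- with_seed(train_config$seed, {
    n <- nrow(X)
    n_val <- floor(train_config$validation_fraction * n)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    train_idx <- setdiff(perm, val_idx)
    check_that(length(train_idx) >= train_config$batch_size, "validation_fraction",
               "leaves fewer training rows than batch_size")
    Xtr <- X[train_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]
    h <- vector("list", epochs)
    for (epoch in seq_len(epochs)) {
      beta <- train_config$kl_weight
      if (train_config$kl_warmup_epochs > 0) {
        beta <- beta * min(1, epoch / train_config$kl_warmup_epochs)
      }
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1L, nrow(Xtr), by = train_config$batch_size)
      sums <- c(recon = 0, kl = 0, total = 0)
      n_used <- 0L
      n_batch <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + train_config$batch_size - 1L, nrow(Xtr))]
        if (length(idx) < 2L) next  # batch norm needs >= 2 rows
        n_batch <- n_batch + 1L
        losses <- vae_train_step(model, Xtr[idx, , drop = FALSE], beta, opt)
        if (!all(vapply(losses, is.finite, logical(1)))) {
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, n_batch),
               call. = FALSE)
        }
        sums <- sums + c(losses$recon, losses$kl, losses$total) * length(idx)
        n_used <- n_used + length(idx)
      }
      row <- data.frame(epoch = epoch, recon = sums[["recon"]] / n_used,
                        kl = sums[["kl"]] / n_used, total = sums[["total"]] / n_used)
      if (has_val) {
        vl <- vae_eval_loss(model, Xval, beta)
        row$val_recon <- vl$recon
        row$val_kl <- vl$kl
        row$val_total <- vl$total
      }
      h[[epoch]] <- row
      if (verbose && (epoch %% 10 == 0 || epoch == epochs)) {
        message(sprintf("epoch %d/%d recon=%.3e kl=%.3f total=%.3e",
                        epoch, epochs, row$recon, row$kl, row$total))
      }
      if (!is.null(checkpoint_dir) && train_config$checkpoint_every > 0 &&
          epoch %% train_config$checkpoint_every == 0) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_checkpoint(model, file.path(checkpoint_dir,
                                         sprintf("epoch-%04d.rds", epoch)))
      }
    }
    out <- do.call(rbind, h)
    attr(out, "val_idx") <- val_idx
    out
  })
  structure(list(model = model, history = history,
                 train_config = train_config), class = "vae_fit")
}

#' @export
print.vae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<vae_fit> %d epoch(s); final recon=%.4e mV^2, KL=%.3f nats\n",
              nrow(x$history), last$recon, last$kl))
  invisible(x)
}

CHECKPOINT_SCHEMA <- "ecgvae-checkpoint-1"

#' Save a model checkpoint
#'
#' Serializes the architecture config, all weights and the batch-norm
#' running statistics under a versioned schema. [load_checkpoint()] of a
#' saved model reproduces encoder and decoder outputs bit-identically.
#'
#' @param model A `vae_model` (or a `vae_fit`, whose model is saved).
#' @param path Output file path.
#' @return `invisible(path)`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "vae_fit")) model <- model$model
  stopifnot(inherits(model, "vae_model"))
  layers <- vae_layers(model)
  state <- lapply(layers, function(l) {
    s <- lapply(l$param_names, function(p) l[[p]])
    names(s) <- l$param_names
    if (l$type == "batchnorm") {
      s$run_mean <- l$run_mean
      s$run_var <- l$run_var
    }
    s
  })
  saveRDS(list(schema = CHECKPOINT_SCHEMA,
               config = unclass(model$config), state = state), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path A file written by [save_checkpoint()]. A schema-version or
#'   architecture mismatch is an explicit error, never a silent
#'   reinterpretation.
#' @return A `vae_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  obj <- readRDS(path)
  check_that(identical(obj$schema, CHECKPOINT_SCHEMA), "schema",
             sprintf("checkpoint schema '%s' does not match supported '%s'",
                     obj$schema %||% "<missing>", CHECKPOINT_SCHEMA))
  cfg <- do.call(model_config, obj$config)
  model <- build_vae(cfg)
  layers <- vae_layers(model)
  check_that(length(layers) == length(obj$state), "checkpoint",
             "layer count does not match the architecture config")
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    s <- obj$state[[i]]
    for (p in l$param_names) {
      check_that(identical(dim(l[[p]]), dim(s[[p]])) &&
                   length(l[[p]]) == length(s[[p]]), "checkpoint",
                 sprintf("parameter '%s' of layer %d has mismatched shape", p, i))
      l[[p]] <- s[[p]]
    }
    if (l$type == "batchnorm") {
      l$run_mean <- s$run_mean
      l$run_var <- s$run_var
    }
  }
  model
}

#' Compare a checkpoint's latent dimension against an expected value
#'
#' Convenience guard used when wiring checkpoints into pipelines: loading a
#' checkpoint whose latent dimension differs from what the caller expects
#' is an error naming both dimensions.
#'
#' @param path Checkpoint path.
#' @param latent_dim Expected latent dimension.
#' @return The loaded `vae_model`, invisibly usable.
#' @export
load_checkpoint_expecting <- function(path, latent_dim) {
  model <- load_checkpoint(path)
  check_that(model$config$latent_dim == latent_dim, "latent_dim",
             sprintf("checkpoint has latent_dim %d but %d was expected",
                     model$config$latent_dim, as.integer(latent_dim)))
  model
}
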