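#' Generate synthetic cycles from the standard-normal prior
#'
#' Draws `n` latent vectors i.i.d. from N(0, I) and decodes each in
#' inference mode — the generative use of the trained model. Reproducible
#' given `seed`.
#'
#' @param model A `vae_model` (or `vae_fit`).
#' @param n Number of cycles to generate; at least 1.
#' @param seed Optional integer seed.
#' @return A [cycle_matrix()] of `n` generated cycles.
#' @export
vae_generate <- function(model, n, seed = NULL) {
  if (inherits(model, "vae_fit")) model <- model$model
  stopifnot(inherits(model, "vae_model"))
  check_that(is.numeric(n) && length(n) == 1L && n >= 1, "n", "must be at least 1")
  n <- as.integer(n)
  Z <- model$config$latent_dim
  z <- with_seed(seed, matrix(rnorm(n * Z), n, Z))
  cycle_matrix(vae_decode(model, z),
               metadata = list(source = "vae_generate", n = n, seed = seed,
                               latent_dim = Z))
}

#' Latent traversal of a single feature
#'
#' Decodes a grid of latent vectors that are identical to `base` except in
#' one component, which sweeps through `values` — the experiment used to
#' inspect what an individual latent feature controls (e.g. the amplitude
#' of a single wave). Row `k` of the result is
#' `decode(base with feature feature_index set to values[k])`.
#'
#' Which wave each feature controls is a property of a particular trained
#' model and is read off the traversal plots by eye; the package makes no
#' automated claim about it.
#'
#' @param model A `vae_model` (or `vae_fit`).
#' @param base Latent vector of length `latent_dim` holding the 24 fixed
#'   features (defaults to the all-zero prior mean).
#' @param feature_index 1-based index of the feature to vary.
#' @param values Grid of values for the varying feature; the default grid
#'   is 7 points over \[-3, 3\], the effective support of the
#'   standard-normal prior.
#' @return A [cycle_matrix()] with `length(values)` rows.
#' @export
vae_traverse <- function(model, base = NULL, feature_index = 1L,
                         values = seq(-3, 3, length.out = 7)) {
  if (inherits(model, "vae_fit")) model <- model$model
  stopifnot(inherits(model, "vae_model"))
  Z <- model$config$latent_dim
  if (is.null(base)) base <- rep(0, Z)
  check_that(length(base) == Z, "base",
             sprintf("length %d does not match latent_dim %d", length(base), Z))
  check_that(is.numeric(feature_index) && length(feature_index) == 1L &&
               feature_index >= 1 && feature_index <= Z, "feature_index",
             sprintf("must lie in 1..%d", Z))
  check_that(length(values) >= 1, "values", "must be non-empty")
  z <- matrix(rep(as.numeric(base), each = length(values)),
              length(values), Z)
  z[, as.integer(feature_index)] <- values
  cycle_matrix(vae_decode(model, z),
               metadata = list(source = "vae_traverse",
                               feature_index = as.integer(feature_index),
                               values = values, base = as.numeric(base)))
}

#' Extract latent features from cycles
#'
#' Returns the encoder mean vectors — the deterministic per-cycle feature
#' representation (no sampling), computed with batch norm in inference
#' mode.
#'
#' @param model A `vae_model` (or `vae_fit`).
#' @param cycles A [cycle_matrix()] or numeric matrix whose row length
#'   matches the model's `input_length`.
#' @return Numeric n x `latent_dim` matrix of latent means.
#' @export
encode_features <- function(model, cycles) {
  if (inherits(model, "vae_fit")) model <- model$model
  stopifnot(inherits(model, "vae_model"))
  X <- as_cycle_values(cycles)
  vae_encode(model, X, training = FALSE)$mean
}
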