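#' Denoising-autoencoder architecture specification
#'
#' Encoder widths default to (32, 16): a 32-unit hidden layer with rectifier
#' activation followed by a 16-dimensional linear bottleneck. The decoder
#' mirrors it (16 -> 32 -> p) with a rectifier after its hidden layer and a
#' linear output layer, so reconstructions of z-scored columns are
#' unbounded. Corruption is additive Gaussian noise of standard deviation
#' `noise_sd` applied to every input column during training.
#'
#' @param input_dim number of covariates p.
#' @param encoder_widths hidden widths of the encoder; the last entry is the
#'   bottleneck dimension (default c(32, 16)).
#' @param noise_sd corruption standard deviation (default 0.1, a mild
#'   perturbation for z-scored / one-hot inputs).
#' @return An object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(input_dim, encoder_widths = c(32, 16),
                             noise_sd = 0.1) {
  stopifnot(input_dim >= 1, length(encoder_widths) >= 1,
            all(encoder_widths >= 1), noise_sd >= 0)
  structure(list(
    input_dim = as.integer(input_dim),
    encoder_widths = as.integer(encoder_widths),
    latent_dim = as.integer(encoder_widths[length(encoder_widths)]),
    noise_sd = noise_sd
  ), class = "autoencoder_spec")
}

# Initialize encoder/decoder parameter sets for a spec. Encoder:
# p -> 32 (ReLU) -> 16 (linear bottleneck). Decoder mirrors: 16 -> 32 (ReLU)
# -> p (linear).
init_autoencoder <- function(spec) {
  w <- spec$encoder_widths
  nw <- length(w)
  enc <- nn_mlp(spec$input_dim,
                hidden = if (nw > 1) w[-nw] else integer(0),
                n_out = spec$latent_dim)
  dec_hidden <- if (nw > 1) rev(w[-nw]) else integer(0)
  dec <- nn_mlp(spec$latent_dim, hidden = dec_hidden, n_out = spec$input_dim)
  list(encoder = enc, decoder = dec)
}

#' Corrupt a covariate matrix with Gaussian noise
#'
#' Adds i.i.d. Normal(0, sigma^2) noise to every cell. With `sigma = 0` the
#' input is returned exactly. Deterministic for a fixed seed.
#'
#' @param x numeric matrix.
#' @param sigma noise standard deviation, >= 0.
#' @param seed optional seed; if NULL the current RNG stream is used (as
#'   inside a seeded training loop).
#' @return A list with `x_tilde` (the corrupted matrix), `sigma`, `seed`.
#' @export
corrupt <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  x_tilde <- if (sigma == 0) x else
    x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x), ncol(x))
  list(x_tilde = x_tilde, sigma = sigma, seed = seed)
}

#' Encode covariates to latent features / decode back
#'
#' Deterministic forward passes through the encoder (to the bottleneck) or
#' decoder (back to input space).
#'
#' @param params an autoencoder parameter set from a fitted model (list with
#'   `encoder` and `decoder` networks).
#' @param x covariate matrix (rows = subjects).
#' @return `encode()`: n x latent matrix; `decode()`: n x p reconstruction.
#' @export
encode <- function(params, x) {
  nn_forward(params$encoder, as.matrix(x), training = FALSE)$out
}

#' @rdname encode
#' @param y latent feature matrix.
#' @export
decode <- function(params, y) {
  nn_forward(params$decoder, as.matrix(y), training = FALSE)$out
}

#' Mean squared reconstruction error
#'
#' Mean over rows of the squared Euclidean distance between each input row
#' and its reconstruction: \eqn{\frac{1}{n}\sum_i \|x_i - x'_i\|^2}.
#'
#' @param x clean input matrix.
#' @param x_prime reconstruction of the same shape.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x, x_prime) {
  x <- as.matrix(x); x_prime <- as.matrix(x_prime)
  stopifnot(identical(dim(x), dim(x_prime)))
  mean(rowSums((x - x_prime)^2))
}

# gradient of reconstruction_loss w.r.t. x_prime
reconstruction_loss_grad <- function(x, x_prime) {
  2 * (x_prime - x) / nrow(x)
}
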