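#' Numerically stable sigmoid
#'
#' Elementwise `1 / (1 + exp(-z))`, computed without overflow for large
#' `|z|` (the large-negative branch goes through `exp(z) / (1 + exp(z))`).
#'
#' @param z numeric vector or matrix.
#' @return Same shape, values in `[0, 1]`.
#' @export
sigmoid <- function(z) {
  out <- z
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Kullback--Leibler divergence between Bernoulli rates
#'
#' The sparsity penalty kernel: `rho*log(rho/rho_hat) +
#' (1-rho)*log((1-rho)/(1-rho_hat))`, natural log.  Both arguments must lie
#' strictly inside `(0, 1)`; callers clip mean activations into
#' `[1e-10, 1 - 1e-10]` beforehand.
#'
#' @param rho target activation rate.
#' @param rho_hat observed mean activation rate (vectorised).
#' @return Non-negative divergence, same length as `rho_hat`.
#' @export
kl_divergence <- function(rho, rho_hat) {
  if (any(rho <= 0 | rho >= 1) || any(rho_hat <= 0 | rho_hat >= 1))
    stop("KL divergence requires rates strictly inside (0, 1)")
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Construct one sparse-autoencoder layer
#'
#' Encoder/decoder weights are untied.  Weights initialise uniformly in
#' `+/- sqrt(6 / (fan_in + fan_out))`, biases at zero.
#'
#' @param n_input input dimension.
#' @param n_hidden hidden dimension.
#' @param rho target mean hidden activation (sparsity target), default 0.2.
#' @param beta weight of the sparsity penalty, default 3.
#' @param lam weight-decay coefficient, default 0.003.
#' @param seed integer RNG seed for the initialisation draw.
#' @return Object of class `autoencoder_layer` with `W_enc` (hidden x
#'   input), `b_enc`, `W_dec` (input x hidden), `b_dec` and the
#'   hyperparameters.
#' @export
autoencoder_layer <- function(n_input, n_hidden, rho = 0.2, beta = 3,
                              lam = 0.003, seed = 1L) {
  stopifnot(rho > 0, rho < 1, beta >= 0, lam >= 0)
  r <- sqrt(6 / (n_input + n_hidden))
  set.seed(seed)
  structure(list(
    W_enc = matrix(stats::runif(n_hidden * n_input, -r, r), n_hidden, n_input),
    b_enc = rep(0, n_hidden),
    W_dec = matrix(stats::runif(n_input * n_hidden, -r, r), n_input, n_hidden),
    b_dec = rep(0, n_input),
    rho = rho, beta = beta, lam = lam,
    n_input = as.integer(n_input), n_hidden = as.integer(n_hidden)),
    class = "autoencoder_layer")
}

#' Encode inputs through one layer
#'
#' @param layer an `autoencoder_layer`.
#' @param x input vector of length `n_input`, or an n x `n_input` matrix of
#'   row vectors.
#' @return Hidden activation(s): `sigmoid(W_enc %*% x + b_enc)`, a vector
#'   or n x `n_hidden` matrix matching the input shape.
#' @export
encode <- function(layer, x) {
  if (is.matrix(x)) {
    if (ncol(x) != layer$n_input)
      stop("input width ", ncol(x), " != layer input size ", layer$n_input)
    sigmoid(sweep(x %*% t(layer$W_enc), 2, layer$b_enc, "+"))
  } else {
    if (length(x) != layer$n_input)
      stop("input length ", length(x), " != layer input size ", layer$n_input)
    as.numeric(sigmoid(layer$W_enc %*% x + layer$b_enc))
  }
}

# forward pass internals shared by cost and gradients; mask (n x hidden,
# already scaled by 1/(1-p)) multiplies hidden activations on the
# reconstruction path only.
.ae_forward <- function(layer, X, mask = NULL) {
  A2 <- sigmoid(sweep(X %*% t(layer$W_enc), 2, layer$b_enc, "+"))
  A2m <- if (is.null(mask)) A2 else A2 * mask
  A3 <- sigmoid(sweep(A2m %*% t(layer$W_dec), 2, layer$b_dec, "+"))
  rho_hat <- pmin(pmax(colMeans(A2), 1e-10), 1 - 1e-10)
  list(A2 = A2, A2m = A2m, A3 = A3, rho_hat = rho_hat)
}

#' Sparse-autoencoder cost
#'
#' Mean over the batch of half the squared reconstruction error, plus the
#' weight-decay term `(lam/2) * sum(W^2)` over both weight matrices (biases
#' excluded), plus `beta * sum_j KL(rho || rho_hat_j)` where `rho_hat_j` is
#' the mean activation of hidden unit j over the batch.
#'
#' @param layer an `autoencoder_layer`.
#' @param X n x `n_input` batch of row-vector inputs.
#' @param mask optional n x `n_hidden` dropout mask (already inverse-scaled)
#'   applied to hidden activations on the reconstruction path; the sparsity
#'   term always uses the unmasked activations.
#' @return Scalar cost.
#' @export
sparse_cost <- function(layer, X, mask = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty batch")
  f <- .ae_forward(layer, X, mask)
  recon <- mean(rowSums((f$A3 - X)^2)) / 2
  decay <- layer$lam / 2 * (sum(layer$W_enc^2) + sum(layer$W_dec^2))
  sparse <- layer$beta * sum(kl_divergence(layer$rho, f$rho_hat))
  recon + decay + sparse
}

#' Analytic gradients of the sparse-autoencoder cost
#'
#' Backpropagation through the two sigmoid layers, including the sparsity
#' penalty's contribution through the batch mean activations.
#'
#' @inheritParams sparse_cost
#' @return List with `W_enc`, `b_enc`, `W_dec`, `b_dec` gradient arrays
#'   shaped like the corresponding parameters.
#' @export
cost_gradients <- function(layer, X, mask = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty batch")
  n <- nrow(X)
  f <- .ae_forward(layer, X, mask)
  delta3 <- (f$A3 - X) * f$A3 * (1 - f$A3)              # n x input
  gW_dec <- t(delta3) %*% f$A2m / n + layer$lam * layer$W_dec
  gb_dec <- colMeans(delta3)
  kl_grad <- layer$beta *
    (-layer$rho / f$rho_hat + (1 - layer$rho) / (1 - f$rho_hat))
  back <- delta3 %*% layer$W_dec                         # n x hidden
  if (!is.null(mask)) back <- back * mask
  delta2 <- (back + matrix(kl_grad, n, layer$n_hidden, byrow = TRUE)) *
    f$A2 * (1 - f$A2)
  gW_enc <- t(delta2) %*% X / n + layer$lam * layer$W_enc
  gb_enc <- colMeans(delta2)
  list(W_enc = gW_enc, b_enc = gb_enc, W_dec = gW_dec, b_dec = gb_dec)
}

#' One stochastic-gradient-descent update
#'
#' `W <- W - eps * dJ/dW` and `b <- b - eps * dJ/db` for all four parameter
#' blocks.
#'
#' @param layer an `autoencoder_layer`.
#' @param gradients list from [cost_gradients()].
#' @param eps learning rate (> 0; 0 is permitted and is the identity).
#' @return The updated layer.
#' @export
sgd_step <- function(layer, gradients, eps) {
  stopifnot(eps >= 0)
  layer$W_enc <- layer$W_enc - eps * gradients$W_enc
  layer$b_enc <- layer$b_enc - eps * gradients$b_enc
  layer$W_dec <- layer$W_dec - eps * gradients$W_dec
  layer$b_dec <- layer$b_dec - eps * gradients$b_dec
  layer
}

#' Inverted-dropout mask
#'
#' Each unit is kept independently with probability `1 - p`; kept entries
#' carry the value `1 / (1 - p)` so the masked activation is unbiased for
#' the unmasked one.  At prediction time no mask is applied.
#'
#' @param shape integer vector: `n` or `c(n, m)`.
#' @param p drop probability in `[0, 1)`.
#' @return Numeric array of the requested shape with entries in
#'   `{0, 1/(1-p)}`.
#' @export
dropout_mask <- function(shape, p) {
  if (p < 0 || p >= 1) stop("dropout probability must lie in [0, 1)")
  keep <- stats::rbinom(prod(shape), 1, 1 - p) / (1 - p)
  if (length(shape) > 1) array(keep, dim = shape) else keep
}

#' Train one sparse autoencoder layer by minibatch SGD
#'
#' Runs `epochs` passes over shuffled minibatches, applying a fresh
#' inverted-dropout mask to the hidden units of each minibatch when
#' `dropout_p > 0`.  Deterministic given the layer's state and the RNG
#' state at entry.
#'
#' @param layer an `autoencoder_layer`.
#' @param X n x `n_input` training matrix.
#' @param epochs full passes over the data (0 leaves the layer untouched).
#' @param learning_rate SGD step size.
#' @param batch_size minibatch size (capped at n).
#' @param dropout_p hidden-unit drop probability during training.
#' @return The trained layer.
#' @export
train_autoencoder <- function(layer, X, epochs = 10, learning_rate = 0.1,
                              batch_size = 32, dropout_p = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  bs <- min(batch_size, n)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      mask <- if (dropout_p > 0)
        dropout_mask(c(length(idx), layer$n_hidden), dropout_p) else NULL
      g <- cost_gradients(layer, X[idx, , drop = FALSE], mask)
      layer <- sgd_step(layer, g, learning_rate)
    }
  }
  layer
}
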