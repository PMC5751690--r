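#' Training configuration
#'
#' @param learning_rate SGD step size for layer-wise pretraining.
#' @param epochs pretraining epochs per layer.
#' @param batch_size SGD minibatch size.
#' @param dropout_p hidden-unit drop probability during pretraining
#'   (default 0.5); dropout is off during fine-tuning and prediction.
#' @param max_finetune_iters L-BFGS iteration cap for fine-tuning.
#' @param rng_seed integer seed controlling every random draw in training.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, epochs = 10, batch_size = 32,
                         dropout_p = 0.5, max_finetune_iters = 200,
                         rng_seed = 1L) {
  stopifnot(learning_rate > 0, dropout_p >= 0, dropout_p < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), dropout_p = dropout_p,
                 max_finetune_iters = as.integer(max_finetune_iters),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Construct a stacked sparse-autoencoder classifier
#'
#' An ordered stack of sigmoid encoder layers (default hidden sizes
#' 500/300/150) topped by a softmax head over `n_classes` labels
#' (3 for solvent accessibility, 15 for contact number).
#'
#' @param n_input width of the windowed feature rows (836 at the default
#'   window 11).
#' @param hidden_sizes integer vector of hidden layer widths.
#' @param n_classes number of output classes.
#' @param rho,beta,lam sparse-autoencoder hyperparameters shared by all
#'   layers (defaults 0.2, 3, 0.003); `lam` also weights the fine-tuning
#'   decay term.
#' @param dropout_p drop probability stored with the model (used during
#'   pretraining only).
#' @param seed integer seed for weight initialisation.
#' @return Object of class `stacked_model` with `trained` stage flag
#'   `"untrained"`.
#' @export
stacked_model <- function(n_input, hidden_sizes = c(500L, 300L, 150L),
                          n_classes, rho = 0.2, beta = 3, lam = 0.003,
                          dropout_p = 0.5, seed = 1L) {
  stopifnot(n_classes >= 2, length(hidden_sizes) >= 1)
  dims <- c(n_input, hidden_sizes)
  layers <- lapply(seq_along(hidden_sizes), function(k)
    autoencoder_layer(dims[k], dims[k + 1], rho = rho, beta = beta,
                      lam = lam, seed = seed + k))
  structure(list(layers = layers,
                 softmax_W = matrix(0, n_classes, hidden_sizes[length(hidden_sizes)]),
                 softmax_b = rep(0, n_classes),
                 n_classes = as.integer(n_classes),
                 lam = lam, dropout_p = dropout_p,
                 trained = "untrained"),
            class = "stacked_model")
}

#' Greedy layer-wise pretraining
#'
#' Trains layer k as a sparse autoencoder (SGD with dropout on its hidden
#' units) on the encoded output of layers `1..k-1`; decoders are discarded
#' afterwards.  Deterministic given `config$rng_seed`.
#'
#' @param model a `stacked_model`.
#' @param X n x `n_input` matrix of windowed feature rows.
#' @param config a [train_config()].
#' @return The pretrained model (`trained = "pretrained"`).
#' @export
greedy_pretrain <- function(model, X, config = train_config()) {
  X <- as.matrix(X)
  if (ncol(X) != model$layers[[1]]$n_input)
    stop("input width ", ncol(X), " != first-layer input size ",
         model$layers[[1]]$n_input)
  set.seed(config$rng_seed)
  cur <- X
  for (k in seq_along(model$layers)) {
    model$layers[[k]] <- train_autoencoder(
      model$layers[[k]], cur,
      epochs = config$epochs, learning_rate = config$learning_rate,
      batch_size = config$batch_size, dropout_p = config$dropout_p)
    cur <- encode(model$layers[[k]], cur)
  }
  for (k in seq_along(model$layers)) {
    model$layers[[k]]$W_dec <- NULL
    model$layers[[k]]$b_dec <- NULL
  }
  model$trained <- "pretrained"
  model
}

# encoder stack forward pass; returns hidden activations per layer
.stack_forward <- function(model, X, masks = NULL) {
  acts <- vector("list", length(model$layers))
  cur <- X
  for (k in seq_along(model$layers)) {
    l <- model$layers[[k]]
    cur <- sigmoid(sweep(cur %*% t(l$W_enc), 2, l$b_enc, "+"))
    if (!is.null(masks)) cur <- cur * masks[[k]]
    acts[[k]] <- cur
  }
  acts
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Forward pass to class probabilities
#'
#' Inputs pass through the sigmoid encoder stack and the softmax head.
#' With `training = TRUE` a fresh inverted-dropout mask is applied to each
#' hidden layer; with `training = FALSE` (prediction) the pass is
#' deterministic and rng-independent.
#'
#' @param model a pretrained or fine-tuned `stacked_model`.
#' @param x input row vector or n x `n_input` matrix.
#' @param training logical; apply dropout masks.
#' @return n x `n_classes` matrix of class probabilities (rows sum to 1).
#' @export
forward <- function(model, x, training = FALSE) {
  if (model$trained == "untrained")
    stop("model must be pretrained before forward passes")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$layers[[1]]$n_input)
    stop("input width ", ncol(X), " != model input size ",
         model$layers[[1]]$n_input)
  masks <- if (training && model$dropout_p > 0)
    lapply(model$layers, function(l)
      dropout_mask(c(nrow(X), l$n_hidden), model$dropout_p))
  else NULL
  acts <- .stack_forward(model, X, masks)
  top <- acts[[length(acts)]]
  .softmax_rows(sweep(top %*% t(model$softmax_W), 2, model$softmax_b, "+"))
}

# ---- fine-tuning objective: cross-entropy + (lam/2) * sum of squared
# weights over encoder matrices and softmax head (biases excluded) ----

#' Flatten all trainable parameters to one vector
#' @param model a `stacked_model`.
#' @return Numeric vector (encoder weights/biases per layer, then softmax).
#' @export
model_parameters <- function(model) {
  unlist(c(lapply(model$layers, function(l) c(as.numeric(l$W_enc), l$b_enc)),
           list(as.numeric(model$softmax_W), model$softmax_b)))
}

#' Write a flat parameter vector back into the model
#' @param model a `stacked_model`.
#' @param par numeric vector as produced by [model_parameters()].
#' @return The updated model.
#' @export
set_model_parameters <- function(model, par) {
  off <- 0L
  take <- function(n) {
    v <- par[(off + 1L):(off + n)]
    off <<- off + n
    v
  }
  for (k in seq_along(model$layers)) {
    l <- model$layers[[k]]
    model$layers[[k]]$W_enc <- matrix(take(l$n_hidden * l$n_input),
                                      l$n_hidden, l$n_input)
    model$layers[[k]]$b_enc <- take(l$n_hidden)
  }
  m <- model$n_classes; h <- ncol(model$softmax_W)
  model$softmax_W <- matrix(take(m * h), m, h)
  model$softmax_b <- take(m)
  stopifnot(off == length(par))
  model
}

#' Fine-tuning objective value (cross-entropy + weight decay)
#'
#' @param model a `stacked_model`.
#' @param X n x `n_input` inputs.
#' @param y integer class labels in `0..n_classes-1`.
#' @return Scalar objective.
#' @export
finetune_objective <- function(model, X, y) {
  P <- forward(model, X, training = FALSE)
  n <- nrow(P)
  ll <- -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-300)))
  decay <- model$lam / 2 *
    (sum(vapply(model$layers, function(l) sum(l$W_enc^2), 0)) +
       sum(model$softmax_W^2))
  ll + decay
}

#' Analytic gradient of the fine-tuning objective
#'
#' Backpropagation through the softmax head and every encoder layer,
#' packed in [model_parameters()] order.
#'
#' @inheritParams finetune_objective
#' @return Numeric gradient vector.
#' @export
finetune_gradient <- function(model, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  acts <- .stack_forward(model, X)
  top <- acts[[length(acts)]]
  P <- .softmax_rows(sweep(top %*% t(model$softmax_W), 2, model$softmax_b, "+"))
  Y <- matrix(0, n, model$n_classes)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  delta <- (P - Y) / n                               # n x M
  gWs <- t(delta) %*% top + model$lam * model$softmax_W
  gbs <- colSums(delta)
  back <- delta %*% model$softmax_W                  # n x h_last
  grads <- vector("list", length(model$layers))
  for (k in rev(seq_along(model$layers))) {
    A <- acts[[k]]
    below <- if (k == 1) X else acts[[k - 1]]
    dZ <- back * A * (1 - A)
    grads[[k]] <- c(as.numeric(t(dZ) %*% below +
                                 model$lam * model$layers[[k]]$W_enc),
                    colSums(dZ))
    back <- dZ %*% model$layers[[k]]$W_enc
  }
  c(unlist(grads), as.numeric(gWs), gbs)
}

#' Fine-tune the stack end-to-end with limited-memory BFGS
#'
#' Jointly optimises all encoder weights and the softmax head against the
#' cross-entropy-plus-decay objective using `stats::optim` L-BFGS-B with
#' analytic gradients (gradient tolerance 1e-5).  Dropout is off during
#' fine-tuning.  The returned objective never exceeds the entry objective.
#'
#' @param model a pretrained `stacked_model`.
#' @param X n x `n_input` inputs.
#' @param y integer class labels in `0..n_classes-1`.
#' @param config a [train_config()] (uses `max_finetune_iters`).
#' @return The fine-tuned model (`trained = "finetuned"`).
#' @export
fine_tune <- function(model, X, y, config = train_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (any(y < 0L | y >= model$n_classes))
    stop("labels must lie in 0..", model$n_classes - 1L)
  if (config$max_finetune_iters > 0L) {
    par0 <- model_parameters(model)
    f0 <- finetune_objective(model, X, y)
    fit <- stats::optim(
      par0,
      fn = function(p) finetune_objective(set_model_parameters(model, p), X, y),
      gr = function(p) finetune_gradient(set_model_parameters(model, p), X, y),
      method = "L-BFGS-B",
      control = list(maxit = config$max_finetune_iters, pgtol = 1e-5))
    if (fit$value <= f0) model <- set_model_parameters(model, fit$par)
  }
  model$trained <- "finetuned"
  model
}

#' Predict labels and class probabilities
#'
#' Argmax over the forward-pass probabilities; exact ties break toward the
#' lowest class index.
#'
#' @param model a fine-tuned (or pretrained, with a warning)
#'   `stacked_model`.
#' @param X n x `n_input` inputs.
#' @param task `"cn15"` or `"sa3"`, controlling the label symbols.
#' @return List with `labels` (a `label_track`) and `probs` (n x M matrix).
#' @export
predict_labels <- function(model, X, task = c("cn15", "sa3")) {
  task <- match.arg(task)
  if (model$trained == "pretrained")
    warning("predicting from a pretrained (not fine-tuned) model")
  P <- forward(model, X, training = FALSE)
  cls <- max.col(P, ties.method = "first") - 1L
  labels <- if (task == "sa3") c("B", "I", "E")[cls + 1L] else cls
  list(labels = label_track(task, labels), probs = P)
}

#' Save / load a trained model
#'
#' @param model a `stacked_model`.
#' @param path file path for the serialized model archive.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "stacked_model"))
  model
}
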