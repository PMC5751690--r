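test_that("sigmoid is stable at extreme arguments and has the known derivative", {
  expect_equal(sigmoid(0), 0.5)
  v <- sigmoid(-1000)
  expect_true(is.finite(v) && v >= 0 && v <= 1e-300)
  expect_equal(sigmoid(1000), 1)
  set.seed(2)
  z <- rnorm(30, sd = 3)
  num <- (sigmoid(z + 1e-6) - sigmoid(z - 1e-6)) / 2e-6
  expect_equal(sigmoid(z) * (1 - sigmoid(z)), num, tolerance = 1e-8)
})

test_that("encode applies sigmoid(W x + b) and matches a loop oracle", {
  lay <- autoencoder_layer(4, 3, seed = 1)
  lay$W_enc[] <- 0; lay$b_enc[] <- 0
  expect_equal(encode(lay, rep(0, 4)), rep(0.5, 3))

  lay1 <- autoencoder_layer(1, 1, seed = 1)
  lay1$W_enc[] <- 1; lay1$b_enc[] <- 0
  expect_equal(encode(lay1, 0), 0.5)

  set.seed(5)
  lay <- autoencoder_layer(6, 4, seed = 5)
  x <- runif(6)
  oracle <- numeric(4)
  for (j in 1:4) {
    s <- lay$b_enc[j]
    for (i in 1:6) s <- s + lay$W_enc[j, i] * x[i]
    oracle[j] <- 1 / (1 + exp(-s))
  }
  expect_equal(encode(lay, x), oracle, tolerance = 1e-12)
  expect_error(encode(lay, runif(5)), "input length")
})

test_that("KL divergence matches the closed form and Gibbs' inequality", {
  expect_equal(kl_divergence(0.2, 0.2), 0)
  expect_equal(kl_divergence(0.2, 0.5), 0.192745, tolerance = 1e-5)
  set.seed(11)
  r <- runif(1000, 0.01, 0.99); rh <- runif(1000, 0.01, 0.99)
  expect_true(all(kl_divergence(r, rh) >= 0))
  expect_error(kl_divergence(0, 0.5), "strictly inside")
})

test_that("sparse cost equals its construction on degenerate and random inputs", {
  lay <- autoencoder_layer(4, 3, lam = 0, beta = 0, seed = 1)
  lay$W_enc[] <- 0; lay$b_enc[] <- 0; lay$W_dec[] <- 0; lay$b_dec[] <- 0
  X <- matrix(0.5, 5, 4)
  expect_equal(sparse_cost(lay, X), 0)   # reconstruction is exactly 0.5

  set.seed(6)
  lay <- autoencoder_layer(6, 4, lam = 0, beta = 0, seed = 6)
  X <- matrix(runif(30), 5, 6)
  # independent elementwise-loop oracle for the reconstruction term
  tot <- 0
  for (i in 1:5) {
    h <- encode(lay, X[i, ])
    recon <- numeric(6)
    for (k in 1:6) {
      s <- lay$b_dec[k]
      for (j in 1:4) s <- s + lay$W_dec[k, j] * h[j]
      recon[k] <- 1 / (1 + exp(-s))
    }
    tot <- tot + sum((recon - X[i, ])^2) / 2
  }
  expect_equal(sparse_cost(lay, X), tot / 5, tolerance = 1e-12)

  # adding the sparsity penalty strictly increases cost when rho_hat != rho
  lay_b <- lay; lay_b$beta <- 3
  expect_gt(sparse_cost(lay_b, X), sparse_cost(lay, X))
  expect_error(sparse_cost(lay, X[0, , drop = FALSE]), "empty batch")
})

test_that("analytic gradients match central differences with terms toggled", {
  set.seed(20)
  cases <- list(c(3, 2), c(6, 4), c(10, 5))
  toggles <- list(c(lam = 0, beta = 0), c(lam = 0.003, beta = 0),
                  c(lam = 0, beta = 3), c(lam = 0.003, beta = 3))
  for (dims in cases) {
    for (tg in toggles) {
      lay <- autoencoder_layer(dims[1], dims[2], lam = tg["lam"],
                               beta = tg["beta"], seed = sum(dims))
      X <- matrix(runif(5 * dims[1]), 5, dims[1])
      g <- cost_gradients(lay, X)
      for (blk in c("W_enc", "b_enc", "W_dec", "b_dec")) {
        gn <- numeric_layer_gradient(lay, X, blk)
        expect_lt(max_rel_err(g[[blk]], gn), 1e-6)
      }
    }
  }
})

test_that("gradient structure: stationary decoder bias and closed-form decay", {
  lay <- autoencoder_layer(4, 3, lam = 0, beta = 0, seed = 2)
  lay$W_enc[] <- 0; lay$b_enc[] <- 0; lay$W_dec[] <- 0; lay$b_dec[] <- 0
  g <- cost_gradients(lay, matrix(0.5, 6, 4))
  expect_equal(g$b_dec, rep(0, 4))

  # decay-only gradient is lam * W elementwise
  set.seed(3)
  lay2 <- autoencoder_layer(4, 3, lam = 0.1, beta = 0, seed = 3)
  lay0 <- lay2; lay0$lam <- 0
  X <- matrix(runif(20), 5, 4)
  d <- cost_gradients(lay2, X)$W_enc - cost_gradients(lay0, X)$W_enc
  expect_equal(d, 0.1 * lay2$W_enc, tolerance = 1e-12)
})

test_that("gradients remain exact under a fixed dropout mask", {
  set.seed(30)
  lay <- autoencoder_layer(6, 4, seed = 30)
  X <- matrix(runif(30), 5, 6)
  mask <- dropout_mask(c(5, 4), 0.5)
  g <- cost_gradients(lay, X, mask)
  for (blk in c("W_enc", "b_enc", "W_dec", "b_dec")) {
    gn <- numeric_layer_gradient(lay, X, blk, mask)
    expect_lt(max_rel_err(g[[blk]], gn), 1e-6)
  }
})

test_that("SGD steps move parameters against the gradient and descend", {
  lay <- autoencoder_layer(5, 3, seed = 4)
  zero <- list(W_enc = lay$W_enc * 0, b_enc = lay$b_enc * 0,
               W_dec = lay$W_dec * 0, b_dec = lay$b_dec * 0)
  expect_equal(sgd_step(lay, zero, 0.5), lay)
  g <- cost_gradients(lay, matrix(runif(25), 5, 5))
  expect_equal(sgd_step(lay, g, 0), lay)

  set.seed(41)
  X <- matrix(runif(40), 8, 5)
  c0 <- sparse_cost(lay, X)
  lay1 <- sgd_step(lay, cost_gradients(lay, X), 0.01)
  expect_lt(sparse_cost(lay1, X), c0)
})

test_that("full-batch descent yields a non-increasing cost sequence", {
  set.seed(50)
  lay <- autoencoder_layer(6, 4, seed = 50)
  X <- matrix(runif(60), 10, 6)
  costs <- numeric(40)
  for (t in 1:40) {
    costs[t] <- sparse_cost(lay, X)
    lay <- sgd_step(lay, cost_gradients(lay, X), 0.05)
  }
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("inverted dropout has the right keep rate and is unbiased", {
  expect_equal(dropout_mask(10, 0), rep(1, 10))
  expect_error(dropout_mask(10, 1), "\\[0, 1\\)")

  set.seed(60)
  m <- dropout_mask(1e5, 0.5)
  expect_equal(mean(m > 0), 0.5, tolerance = 0.01)
  expect_true(all(m %in% c(0, 2)))

  # E[mask * a] = a within Monte-Carlo error
  a <- 0.7
  expect_equal(mean(m * a), a, tolerance = 0.02)
})

test_that("sparsity pressure drives mean activations to the target rho", {
  set.seed(70)
  X <- matrix(runif(200 * 8), 200, 8)
  lay <- autoencoder_layer(8, 5, rho = 0.2, beta = 3, lam = 0.003, seed = 71)
  lay <- train_autoencoder(lay, X, epochs = 200, learning_rate = 0.5,
                           batch_size = 200, dropout_p = 0)
  rho_hat <- colMeans(encode(lay, X))
  expect_true(all(abs(rho_hat - 0.2) < 0.1))
})
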