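test_that("encoding with zero weights gives 0.5 everywhere (sigmoid of 0)", {
  w <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
            W2 = matrix(0, 4, 3), b2 = rep(0, 4))
  expect_equal(as.vector(sae_encode(c(0.2, 0.9, 0.1, 0.4), w)), rep(0.5, 3))
})

test_that("a 2x2 toy layer matches a hand matrix-multiply oracle", {
  w <- list(W1 = matrix(c(1, -1, 2, 0.5), 2, 2), b1 = c(0.1, -0.2),
            W2 = matrix(c(0.3, 0, -1, 1), 2, 2), b2 = c(0, 0.5))
  x <- c(1, -1)
  z1 <- c(1 * 1 + 2 * (-1) + 0.1, -1 * 1 + 0.5 * (-1) - 0.2)
  h_hand <- 1 / (1 + exp(-z1))
  h <- as.vector(sae_encode(x, w))
  expect_equal(h, h_hand, tolerance = 1e-14)
  xhat <- sae_decode(h, w)
  expect_length(as.vector(xhat), 2L) # auto-encoding shape contract
  expect_error(sae_encode(c(1, 2, 3), w), "width")
})

test_that("with both penalties off the cost is the plain mean squared reconstruction error", {
  set.seed(1)
  w <- spikesae:::sae_init_weights(5, 3, seed = 1)
  X <- matrix(runif(20), 4, 5)
  ev <- sae_cost_and_grad(spikesae:::sae_pack(w), X, 5, 3, lambda = 0, beta = 0)
  H <- sae_encode(X, w)
  Xhat <- sae_decode(H, w)
  expect_equal(ev$cost, sum((X - Xhat)^2) / (2 * nrow(X)), tolerance = 1e-12)
})

test_that("the sparsity term vanishes when every hidden mean activation equals the target", {
  rho <- 0.05
  # zero weights with b1 = logit(rho) pin all activations at exactly rho
  w <- list(W1 = matrix(0, 3, 4), b1 = rep(log(rho / (1 - rho)), 3),
            W2 = matrix(0.1, 4, 3), b2 = rep(0, 4),
            n_visible = 4L, n_hidden = 3L)
  X <- matrix(runif(8), 2, 4)
  theta <- spikesae:::sae_pack(w)
  with_beta <- sae_cost_and_grad(theta, X, 4, 3, lambda = 0, beta = 0.1, rho = rho)
  no_beta <- sae_cost_and_grad(theta, X, 4, 3, lambda = 0, beta = 0)
  expect_equal(with_beta$cost, no_beta$cost, tolerance = 1e-10)
})

test_that("the auto-encoder gradient matches central finite differences", {
  set.seed(2)
  w <- spikesae:::sae_init_weights(4, 3, seed = 2)
  X <- matrix(runif(20), 5, 4)
  theta <- spikesae:::sae_pack(w)
  fn <- function(th) sae_cost_and_grad(th, X, 4, 3, lambda = 0.01, beta = 0.1, rho = 0.05)
  expect_lt(rel_grad_err(fn(theta)$grad, fd_gradient(fn, theta)), 1e-6)
})

test_that("a single repeated vector is memorized to low reconstruction error", {
  set.seed(3)
  x <- runif(6)
  X <- matrix(rep(x, 10), 10, byrow = TRUE)
  cfg <- sae_config(layer_sizes = c(6, 8, 4), l2_weight = 0, sparsity_weight = 0,
                    unsup_epochs = 400)
  w <- train_sae(X, 8, cfg, seed = 3)
  err <- mean((X - sae_decode(sae_encode(X, w), w))^2)
  expect_lt(err, 1e-3)
})

test_that("the scg cost trajectory is non-increasing and ends below its start", {
  set.seed(4)
  X <- matrix(runif(60), 10, 6)
  cfg <- sae_config(layer_sizes = c(6, 4, 3), unsup_epochs = 150)
  w <- train_sae(X, 4, cfg, seed = 4)
  traj <- w$trajectory
  expect_lte(traj[length(traj)], traj[1])
  expect_true(all(diff(traj) <= 1e-12))
})

test_that("the sparsity penalty pulls mean hidden activation toward the target", {
  set.seed(5)
  X <- matrix(runif(160), 20, 8)
  rho <- 0.05
  mean_act <- function(beta) {
    cfg <- sae_config(layer_sizes = c(8, 6, 3), l2_weight = 1e-4,
                      sparsity_weight = beta, sparsity_target = rho,
                      unsup_epochs = 200)
    w <- train_sae(X, 6, cfg, seed = 5)
    mean(sae_encode(X, w))
  }
  expect_lt(abs(mean_act(0.1) - rho), abs(mean_act(0) - rho))
})

test_that("gradient descent is available as the alternative optimizer", {
  set.seed(6)
  X <- matrix(runif(40), 8, 5)
  cfg <- sae_config(layer_sizes = c(5, 3, 2), optimizer = "gd", lr = 0.5,
                    unsup_epochs = 100)
  w <- train_sae(X, 3, cfg, seed = 6)
  expect_lt(w$trajectory[100], w$trajectory[1])
})

test_that("greedy stacking trains layer 2 on exactly the layer-1 code", {
  set.seed(7)
  X <- matrix(runif(120), 10, 12)
  cfg <- sae_config(layer_sizes = c(12, 6, 4), unsup_epochs = 50)
  stack <- stack_pretrain(X, cfg, seed = 7)
  expect_equal(stack$layer2$n_visible, 6L)
  expect_equal(ncol(encode_stack(X, stack)), 4L)
  # retraining layer 2 separately on encode(X, layer1) reproduces it bitwise
  H1 <- sae_encode(X, stack$layer1)
  l2 <- train_sae(H1, 4, cfg, seed = spikesae:::derive_seed(7, 2L))
  expect_identical(stack$layer2$W1, l2$W1)
  expect_identical(stack$layer2$b2, l2$b2)
})

test_that("identical seeds give bitwise-identical trained stacks; codes are finite", {
  set.seed(8)
  X <- matrix(runif(100), 10, 10)
  cfg <- sae_config(layer_sizes = c(10, 5, 3), unsup_epochs = 40)
  s1 <- stack_pretrain(X, cfg, seed = 1)
  s2 <- stack_pretrain(X, cfg, seed = 1)
  expect_identical(s1$layer1$W1, s2$layer1$W1)
  expect_identical(s1$layer2$W2, s2$layer2$W2)
  expect_true(all(is.finite(encode_stack(X, s1))))
})

test_that("fine-tuning in head-only scope leaves the encoder bitwise unchanged", {
  ds <- make_toy_dataset(n_train = 5, width = 12, seed = 9)
  cfg <- sae_config(layer_sizes = c(12, 6, 4), unsup_epochs = 40, sup_epochs = 60,
                    fine_tune_scope = "head_only")
  stack <- stack_pretrain(ds$train, cfg, seed = 9)
  ft <- fine_tune(stack, ds$train, NULL, ds$train_labels, config = cfg)
  expect_identical(ft$stack$layer2$W1, stack$layer2$W1)
  expect_identical(ft$stack$layer2$b1, stack$layer2$b1)
  cfg_top <- sae_config(layer_sizes = c(12, 6, 4), unsup_epochs = 40, sup_epochs = 60,
                        fine_tune_scope = "top")
  ft_top <- fine_tune(stack, ds$train, NULL, ds$train_labels, config = cfg_top)
  expect_false(identical(ft_top$stack$layer2$W1, stack$layer2$W1))
})

test_that("fine-tuning cross-entropy decreases and separable toy data reaches 100% train accuracy", {
  ds <- make_toy_dataset(n_train = 6, width = 12, seed = 10)
  cfg <- sae_config(layer_sizes = c(12, 8, 5), unsup_epochs = 60, sup_epochs = 150)
  clf <- train_rhythm_classifier(ds, cfg, seed = 10)
  traj <- clf$trajectory
  expect_lte(traj[length(traj)], traj[1])
  expect_equal(predict(clf, ds$train), ds$train_labels)
})

test_that("fine-tuning rejects out-of-range labels", {
  ds <- make_toy_dataset(n_train = 3, width = 8, seed = 11)
  cfg <- sae_config(layer_sizes = c(8, 4, 3), unsup_epochs = 20, sup_epochs = 20)
  stack <- stack_pretrain(ds$train, cfg, seed = 11)
  expect_error(fine_tune(stack, ds$train, NULL, rep(5L, nrow(ds$train)), cfg),
               "labels")
})

test_that("a saved model reloads bit-exactly", {
  ds <- make_toy_dataset(n_train = 4, width = 10, seed = 12)
  cfg <- sae_config(layer_sizes = c(10, 5, 3), unsup_epochs = 30, sup_epochs = 40)
  clf <- train_rhythm_classifier(ds, cfg, seed = 12)
  f <- tempfile(fileext = ".json")
  save_model(clf, f)
  back <- load_model(f)
  expect_equal(back$theta, clf$theta, tolerance = 1e-15)
  expect_equal(back$stack$layer1$W1, clf$stack$layer1$W1, tolerance = 1e-15)
  expect_identical(predict(back, ds$test), predict(clf, ds$test))
})
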