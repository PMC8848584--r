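#' Configuration of the stacked sparse auto-encoder
#'
#' Defaults follow the study-standard network: 1024 inputs, hidden layers
#' of 1224 and 824 units (the 824-wide code of the second layer is the
#' learned feature), L2 weight decay 0.01, sparsity weight 0.1, 1000
#' unsupervised and 1000 supervised epochs, logistic sigmoid activations,
#' and full-batch scaled conjugate gradient ("scg") training.
#'
#' @param layer_sizes integer vector `(input, hidden1, hidden2)`.
#' @param l2_weight L2 weight-decay coefficient (lambda, >= 0).
#' @param sparsity_weight sparsity penalty coefficient (beta, >= 0).
#' @param sparsity_target target mean hidden activation (rho, in (0, 1)).
#' @param unsup_epochs,sup_epochs optimizer iteration budgets for the
#'   greedy pre-training and the supervised fine-tuning.
#' @param optimizer `"scg"` (default) or `"gd"`.
#' @param lr learning rate (gd only).
#' @param fine_tune_scope `"top"` (softmax head plus the top encoder
#'   layer, default) or `"head_only"`.
#' @param seed RNG seed for weight initialization.
#' @return object of class `sae_config`.
#' @export
sae_config <- function(layer_sizes = c(1024L, 1224L, 824L),
                       l2_weight = 0.01, sparsity_weight = 0.1,
                       sparsity_target = 0.05,
                       unsup_epochs = 1000L, sup_epochs = 1000L,
                       optimizer = c("scg", "gd"), lr = 0.5,
                       fine_tune_scope = c("top", "head_only"),
                       seed = NULL) {
  optimizer <- match.arg(optimizer)
  fine_tune_scope <- match.arg(fine_tune_scope)
  if (l2_weight < 0 || sparsity_weight < 0) {
    stop("penalty weights must be >= 0", call. = FALSE)
  }
  if (sparsity_target <= 0 || sparsity_target >= 1) {
    stop("sparsity_target must lie in (0, 1)", call. = FALSE)
  }
  if (any(layer_sizes <= 0)) stop("layer sizes must be positive", call. = FALSE)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 l2_weight = l2_weight, sparsity_weight = sparsity_weight,
                 sparsity_target = sparsity_target,
                 unsup_epochs = as.integer(unsup_epochs),
                 sup_epochs = as.integer(sup_epochs),
                 optimizer = optimizer, lr = lr,
                 fine_tune_scope = fine_tune_scope, seed = seed),
            class = "sae_config")
}

# --- parameter packing for one auto-encoder layer ------------------------

sae_init_weights <- function(n_visible, n_hidden, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lim <- sqrt(6 / (n_visible + n_hidden))
  list(W1 = matrix(stats::runif(n_hidden * n_visible, -lim, lim), n_hidden, n_visible),
       b1 = numeric(n_hidden),
       W2 = matrix(stats::runif(n_visible * n_hidden, -lim, lim), n_visible, n_hidden),
       b2 = numeric(n_visible),
       n_visible = n_visible, n_hidden = n_hidden)
}

sae_pack <- function(w) c(w$W1, w$b1, w$W2, w$b2)

sae_unpack <- function(theta, n_visible, n_hidden) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(n_hidden * n_visible)], n_hidden, n_visible)
  i <- i + n_hidden * n_visible
  b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  W2 <- matrix(theta[i + seq_len(n_visible * n_hidden)], n_visible, n_hidden)
  i <- i + n_visible * n_hidden
  b2 <- theta[i + seq_len(n_visible)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
       n_visible = n_visible, n_hidden = n_hidden)
}

#' Encode / decode with one auto-encoder layer
#'
#' `sae_encode` maps inputs to hidden activations
#' `h = sigmoid(W1 x + b1)`; `sae_decode` maps hidden activations back to
#' reconstructions `sigmoid(W2 h + b2)`.
#'
#' @param x numeric vector or matrix (rows = samples) matching the layer's
#'   input width.
#' @param weights layer weights as returned by [train_sae()] (components
#'   `W1`, `b1`, `W2`, `b2`).
#' @return numeric matrix of activations (rows = samples).
#' @examples
#' w <- spikesae:::sae_init_weights(4, 2, seed = 1)
#' sae_encode(runif(4), w)
#' @export
sae_encode <- function(x, weights) {
  X <- as_row_matrix(x)
  if (ncol(X) != ncol(weights$W1)) {
    stop(sprintf("input width %d does not match encoder width %d",
                 ncol(X), ncol(weights$W1)), call. = FALSE)
  }
  sigmoid(sweep(X %*% t(weights$W1), 2L, weights$b1, "+"))
}

#' @rdname sae_encode
#' @param h hidden activations (vector or matrix).
#' @export
sae_decode <- function(h, weights) {
  H <- as_row_matrix(h)
  if (ncol(H) != ncol(weights$W2)) {
    stop(sprintf("hidden width %d does not match decoder width %d",
                 ncol(H), ncol(weights$W2)), call. = FALSE)
  }
  sigmoid(sweep(H %*% t(weights$W2), 2L, weights$b2, "+"))
}

#' Sparse auto-encoder cost and gradient
#'
#' The training objective of one layer: mean over the batch of half the
#' squared reconstruction error, plus an L2 penalty `lambda/2 * sum(W^2)`
#' over both weight matrices, plus a sparsity penalty
#' `beta * sum_j KL(rho || rho_bar_j)` where `rho_bar_j` is the mean
#' activation of hidden unit `j` over the batch. Gradients are exact
#' backpropagation including both penalties (verified against central
#' finite differences in the test suite).
#'
#' @param theta packed parameter vector (`W1`, `b1`, `W2`, `b2`).
#' @param X batch matrix, rows = samples, values in \[0, 1\].
#' @param n_visible,n_hidden layer widths.
#' @param lambda L2 weight.
#' @param beta sparsity weight.
#' @param rho sparsity target.
#' @return list with `cost` (scalar) and `grad` (packed vector).
#' @export
sae_cost_and_grad <- function(theta, X, n_visible, n_hidden,
                              lambda = 0.01, beta = 0.1, rho = 0.05) {
  X <- as_row_matrix(X)
  if (nrow(X) == 0L) stop("empty batch", call. = FALSE)
  w <- sae_unpack(theta, n_visible, n_hidden)
  m <- nrow(X)
  H <- sigmoid(sweep(X %*% t(w$W1), 2L, w$b1, "+"))
  Xhat <- sigmoid(sweep(H %*% t(w$W2), 2L, w$b2, "+"))
  resid <- Xhat - X
  cost <- sum(resid * resid) / (2 * m) +
    lambda / 2 * (sum(w$W1^2) + sum(w$W2^2))
  rho_bar <- colMeans(H)
  if (beta > 0) {
    rb <- pmin(pmax(rho_bar, 1e-10), 1 - 1e-10)
    cost <- cost + beta * sum(rho * log(rho / rb) +
                                (1 - rho) * log((1 - rho) / (1 - rb)))
  }
  if (!is.finite(cost)) stop("non-finite auto-encoder cost", call. = FALSE)
  delta_out <- (resid / m) * Xhat * (1 - Xhat)
  gW2 <- t(delta_out) %*% H + lambda * w$W2
  gb2 <- colSums(delta_out)
  back <- delta_out %*% w$W2
  if (beta > 0) {
    rb <- pmin(pmax(rho_bar, 1e-10), 1 - 1e-10)
    sparse_grad <- beta * (-rho / rb + (1 - rho) / (1 - rb)) / m
    back <- sweep(back, 2L, sparse_grad, "+")
  }
  delta_hid <- back * H * (1 - H)
  gW1 <- t(delta_hid) %*% X + lambda * w$W1
  gb1 <- colSums(delta_hid)
  list(cost = cost, grad = c(gW1, gb1, gW2, gb2))
}

#' Train one sparse auto-encoder layer
#'
#' Full-batch optimization of [sae_cost_and_grad()] from a seeded
#' symmetric-uniform initialization. With the default `"scg"` optimizer
#' the recorded cost trajectory is non-increasing (rejected steps leave
#' the iterate unchanged).
#'
#' @param X training matrix, rows in \[0, 1\].
#' @param n_hidden hidden-layer width.
#' @param config `sae_config` supplying penalties, epochs, optimizer.
#' @param seed weight-initialization seed (overrides `config$seed`).
#' @return layer weights (list `W1`, `b1`, `W2`, `b2`, widths) with a
#'   `cost_trajectory` attribute-like element `trajectory`.
#' @export
train_sae <- function(X, n_hidden, config = sae_config(), seed = NULL) {
  X <- as_row_matrix(X)
  n_visible <- ncol(X)
  if (is.null(seed)) seed <- config$seed
  w0 <- sae_init_weights(n_visible, n_hidden, seed = seed)
  fn <- function(theta) {
    sae_cost_and_grad(theta, X, n_visible, n_hidden,
                      lambda = config$l2_weight,
                      beta = config$sparsity_weight,
                      rho = config$sparsity_target)
  }
  fit <- run_optimizer(fn, sae_pack(w0), optimizer = config$optimizer,
                       max_iter = config$unsup_epochs, lr = config$lr)
  w <- sae_unpack(fit$par, n_visible, n_hidden)
  w$trajectory <- fit$trajectory
  w
}

#' Greedy layer-wise pre-training of the two-layer stack
#'
#' Trains the first auto-encoder on the normalized input matrix, encodes
#' the inputs with it, and trains the second auto-encoder on those hidden
#' activations. The second layer's code (824-wide by default) is the
#' learned representation passed to the classifier.
#'
#' @param X normalized training matrix (rows = sequences).
#' @param config `sae_config`; `layer_sizes[2:3]` give the hidden widths.
#' @param seed base seed; the two layers use derived seeds.
#' @return object of class `sae_stack`: list with `layer1`, `layer2`,
#'   `config`.
#' @export
stack_pretrain <- function(X, config = sae_config(), seed = NULL) {
  X <- as_row_matrix(X)
  if (ncol(X) != config$layer_sizes[1]) {
    stop(sprintf("input width %d does not match configured input size %d",
                 ncol(X), config$layer_sizes[1]), call. = FALSE)
  }
  if (is.null(seed)) seed <- if (is.null(config$seed)) 0L else config$seed
  layer1 <- train_sae(X, config$layer_sizes[2], config,
                      seed = derive_seed(seed, 1L))
  H1 <- sae_encode(X, layer1)
  layer2 <- train_sae(H1, config$layer_sizes[3], config,
                      seed = derive_seed(seed, 2L))
  structure(list(layer1 = layer1, layer2 = layer2, config = config),
            class = "sae_stack")
}

#' Encode inputs with the full stack
#'
#' @param x input vector or matrix (rows = sequences).
#' @param stack an `sae_stack`.
#' @return code matrix (rows = sequences, columns = top hidden units).
#' @export
encode_stack <- function(x, stack) {
  sae_encode(sae_encode(x, stack$layer1), stack$layer2)
}
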