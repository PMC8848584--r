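#' Softmax class probabilities
#'
#' `p_j` proportional to `exp(theta_j' x)`, normalized to sum to 1.
#' Logits are shifted by their maximum before exponentiation, which
#' leaves the probabilities unchanged but avoids overflow.
#'
#' @param theta `k x d` parameter matrix, one row per class.
#' @param x feature vector of length `d`, or a matrix with `d` columns
#'   (rows = samples).
#' @return probability vector of length `k` (or `n x k` matrix).
#' @examples
#' softmax_predict(matrix(0, 4, 3), c(1, 2, 3))  # uniform 1/4
#' @export
softmax_predict <- function(theta, x) {
  X <- as_row_matrix(x)
  if (ncol(X) != ncol(theta)) {
    stop(sprintf("feature length %d does not match theta width %d",
                 ncol(X), ncol(theta)), call. = FALSE)
  }
  Z <- X %*% t(theta)
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  if (is.matrix(x)) P else drop(P)
}

#' Predicted labels under a softmax model
#'
#' Argmax of the class probabilities; ties resolve to the lowest label.
#'
#' @inheritParams softmax_predict
#' @return integer labels in `0:(k-1)`.
#' @export
softmax_classify <- function(theta, x) {
  P <- as_row_matrix(softmax_predict(theta, x))
  apply(P, 1L, which.max) - 1L
}

#' Softmax cross-entropy cost and gradient
#'
#' Negative mean log-likelihood of the true classes under the softmax
#' model (the multinomial cross-entropy). At `theta = 0` the cost equals
#' `log(k)` for any dataset. The gradient is exact (checked against
#' central finite differences in the test suite).
#'
#' @param theta `k x d` parameter matrix (or its packed vector).
#' @param X `n x d` feature matrix.
#' @param y integer labels in `0:(k-1)`.
#' @param k number of classes.
#' @return list with `cost` and `grad` (same shape as `theta` if a matrix
#'   was supplied, packed vector otherwise).
#' @export
softmax_cost_and_grad <- function(theta, X, y, k = 4L) {
  X <- as_row_matrix(X)
  n <- nrow(X)
  if (n == 0L) stop("empty batch", call. = FALSE)
  if (length(y) != n) stop("length of y does not match rows of X", call. = FALSE)
  if (any(y < 0 | y > k - 1L)) stop("labels must lie in 0..k-1", call. = FALSE)
  was_matrix <- is.matrix(theta)
  th <- if (was_matrix) theta else matrix(theta, nrow = k)
  Z <- X %*% t(th)
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  idx <- cbind(seq_len(n), y + 1L)
  cost <- -mean(log(pmax(P[idx], 1e-300)))
  Y <- matrix(0, n, k)
  Y[idx] <- 1
  G <- t(P - Y) %*% X / n
  list(cost = cost, grad = if (was_matrix) G else as.numeric(G))
}

#' Train a softmax classifier
#'
#' Full-batch optimization of [softmax_cost_and_grad()]; a bias is added
#' by augmenting the features with a constant 1 column when
#' `intercept = TRUE`.
#'
#' @param X `n x d` feature matrix.
#' @param y integer labels in `0:(k-1)`.
#' @param k number of classes.
#' @param epochs optimizer iterations.
#' @param optimizer `"scg"` or `"gd"`.
#' @param lr learning rate (gd only).
#' @param intercept add a bias column (default `TRUE`).
#' @return list with `theta` (`k x d(+1)`), `intercept`, `trajectory`.
#' @export
train_softmax <- function(X, y, k = 4L, epochs = 200L,
                          optimizer = c("scg", "gd"), lr = 0.5,
                          intercept = TRUE) {
  optimizer <- match.arg(optimizer)
  X <- as_row_matrix(X)
  if (intercept) X <- cbind(X, 1)
  fn <- function(theta) softmax_cost_and_grad(theta, X, y, k)
  fit <- run_optimizer(fn, numeric(k * ncol(X)), optimizer = optimizer,
                       max_iter = epochs, lr = lr)
  list(theta = matrix(fit$par, nrow = k), intercept = intercept,
       trajectory = fit$trajectory)
}

#' K-nearest-neighbour baseline
#'
#' Euclidean distance, majority vote; vote ties resolve to the smallest
#' label (deterministic).
#'
#' @param train_x,train_y training feature matrix and integer labels.
#' @param test_x test feature matrix.
#' @param k_neighbors neighbourhood size (default 5).
#' @return integer predictions for the test rows.
#' @export
knn_baseline <- function(train_x, train_y, test_x, k_neighbors = 5L) {
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1", call. = FALSE)
  train_x <- as_row_matrix(train_x)
  test_x <- as_row_matrix(test_x)
  train_y <- as.integer(train_y)
  tx2 <- rowSums(train_x^2)
  apply(test_x, 1L, function(q) {
    d2 <- tx2 - 2 * drop(train_x %*% q) # + const |q|^2, irrelevant for order
    nb <- train_y[order(d2)[seq_len(min(k_neighbors, length(d2)))]]
    votes <- table(nb)
    as.integer(names(votes)[which.max(votes)]) # which.max: first (smallest label)
  })
}

#' Support-vector-machine baseline
#'
#' Soft-margin kernel SVM via `e1071::svm` (libsvm; multiclass by
#' pairwise voting).
#'
#' @inheritParams knn_baseline
#' @param kernel kernel name, default `"radial"`.
#' @param C cost parameter, default 1.
#' @return integer predictions for the test rows.
#' @export
svm_baseline <- function(train_x, train_y, test_x, kernel = "radial", C = 1) {
  fit <- e1071::svm(as_row_matrix(train_x), factor(train_y),
                    kernel = kernel, cost = C, scale = FALSE)
  as.integer(as.character(stats::predict(fit, as_row_matrix(test_x))))
}
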