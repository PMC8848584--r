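#' Supervised fine-tuning of the stack with a softmax head
#'
#' Optimizes the multinomial cross-entropy of a softmax classifier over
#' the fused features (code plus scaled scalars plus a bias input). With
#' `config$fine_tune_scope = "top"` (default) the top encoder layer's
#' weights are updated jointly with the softmax parameters; with
#' `"head_only"` the encoder is frozen bitwise and only the head moves.
#'
#' @param stack pre-trained `sae_stack`.
#' @param X normalized training matrix (rows = sequences).
#' @param extra matrix of scaled scalar features to fuse (0 columns or
#'   `NULL` for code-only).
#' @param labels integer class labels in `0:(k-1)`.
#' @param config `sae_config` (supplies `sup_epochs`, optimizer, scope).
#' @param k number of classes.
#' @param seed seed for the softmax-head initialization. The head starts
#'   at small random values rather than zero: with balanced classes and
#'   (near-)constant codes, zero parameters are an exact saddle of the
#'   cross-entropy at which every gradient vanishes.
#' @return list with `stack` (layer2 possibly updated), `theta`
#'   (softmax parameters, `k x (code + extra + 1)`), `trajectory`
#'   (cross-entropy per epoch), `scope`.
#' @export
fine_tune <- function(stack, X, extra, labels, config = stack$config, k = 4L,
                      seed = 0L) {
  X <- as_row_matrix(X)
  n <- nrow(X)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels > k - 1L)) {
    stop("labels must lie in 0..k-1", call. = FALSE)
  }
  if (is.null(extra)) extra <- matrix(0, n, 0L)
  extra <- as.matrix(extra)
  H1 <- sae_encode(X, stack$layer1)
  h1 <- ncol(H1)
  h2 <- stack$layer2$n_hidden
  q <- ncol(extra)
  d <- h2 + q + 1L # fused width plus bias input
  scope <- config$fine_tune_scope
  n_theta <- k * d
  if (!is.null(seed)) set.seed(seed)
  pack0 <- c(stats::rnorm(n_theta, 0, 0.01),
             if (scope == "top") c(stack$layer2$W1, stack$layer2$b1))
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  fn <- function(par) {
    th <- matrix(par[seq_len(n_theta)], nrow = k)
    if (scope == "top") {
      i <- n_theta
      W12 <- matrix(par[i + seq_len(h2 * h1)], h2, h1); i <- i + h2 * h1
      b12 <- par[i + seq_len(h2)]
    } else {
      W12 <- stack$layer2$W1
      b12 <- stack$layer2$b1
    }
    code <- sigmoid(sweep(H1 %*% t(W12), 2L, b12, "+"))
    F <- cbind(code, extra, 1)
    Z <- F %*% t(th)
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z)
    P <- E / rowSums(E)
    cost <- -mean(log(pmax(P[cbind(seq_len(n), labels + 1L)], 1e-300)))
    dZ <- (P - Y) / n
    gth <- t(dZ) %*% F
    if (scope == "top") {
      dF <- dZ %*% th
      dcode <- dF[, seq_len(h2), drop = FALSE] * code * (1 - code)
      gW12 <- t(dcode) %*% H1
      gb12 <- colSums(dcode)
      list(cost = cost, grad = c(gth, gW12, gb12))
    } else {
      list(cost = cost, grad = as.numeric(gth))
    }
  }
  fit <- run_optimizer(fn, pack0, optimizer = config$optimizer,
                       max_iter = config$sup_epochs, lr = config$lr)
  theta <- matrix(fit$par[seq_len(n_theta)], nrow = k)
  out_stack <- stack
  if (scope == "top") {
    i <- n_theta
    out_stack$layer2$W1 <- matrix(fit$par[i + seq_len(h2 * h1)], h2, h1)
    i <- i + h2 * h1
    out_stack$layer2$b1 <- fit$par[i + seq_len(h2)]
  }
  list(stack = out_stack, theta = theta, trajectory = fit$trajectory,
       scope = scope)
}

#' Train the full rhythm classifier on a labeled dataset
#'
#' End-to-end convenience wrapper: greedy pre-training of the stacked
#' sparse auto-encoder on the training matrix, computation of the two
#' scalar features, scaler fitting on the training set only, and
#' supervised fine-tuning of the softmax head over the fused features.
#'
#' @param dataset an `isi_dataset`.
#' @param config `sae_config`; `layer_sizes[1]` must match the sequence
#'   length.
#' @param include_cov,include_apen which scalar features to fuse
#'   (both `TRUE` = the full fused configuration; both `FALSE` =
#'   code-only).
#' @param seed base RNG seed for weight initialization.
#' @param stack optionally, an already pre-trained `sae_stack` to reuse
#'   (e.g. across ablation configurations).
#' @param scaler_method scaling for the fused scalars (default
#'   `"minmax"` over the training set).
#' @return object of class `rhythm_classifier`.
#' @export
train_rhythm_classifier <- function(dataset, config = sae_config(),
                                    include_cov = TRUE, include_apen = TRUE,
                                    seed = 0L, stack = NULL,
                                    scaler_method = "minmax") {
  X <- dataset$train
  if (is.null(stack)) stack <- stack_pretrain(X, config, seed = seed)
  feats <- compute_features(X)
  scaler <- fit_scaler(feats, method = scaler_method)
  scaled <- apply_scaler(as.matrix(feats), scaler)
  extra <- NULL
  if (include_cov) extra <- cbind(extra, scaled[, 1L])
  if (include_apen) extra <- cbind(extra, scaled[, 2L])
  ft <- fine_tune(stack, X, extra, dataset$train_labels, config = config,
                  seed = derive_seed(seed, 3L))
  structure(list(stack = ft$stack, theta = ft$theta, scaler = scaler,
                 include_cov = include_cov, include_apen = include_apen,
                 trajectory = ft$trajectory,
                 class_names = dataset$class_names, config = config),
            class = "rhythm_classifier")
}

#' @export
print.rhythm_classifier <- function(x, ...) {
  cat(sprintf("rhythm_classifier: code width %d, fused scalars: %s\n",
              x$stack$layer2$n_hidden,
              paste(c(if (x$include_cov) "cov", if (x$include_apen) "apen",
                      if (!x$include_cov && !x$include_apen) "none"),
                    collapse = "+")))
  invisible(x)
}

#' Predict rhythm classes for normalized ISI sequences
#'
#' @param object a `rhythm_classifier`.
#' @param newdata matrix of normalized sequences (rows), width matching
#'   the training sequences.
#' @param type `"class"` (integer labels, default) or `"prob"`.
#' @param ... unused.
#' @return integer labels in 0-3 or an `n x 4` probability matrix.
#' @export
predict.rhythm_classifier <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_row_matrix(newdata)
  code <- encode_stack(X, object$stack)
  extra <- NULL
  if (object$include_cov || object$include_apen) {
    feats <- compute_features(X)
    scaled <- apply_scaler(as.matrix(feats), object$scaler)
    if (object$include_cov) extra <- cbind(extra, scaled[, 1L])
    if (object$include_apen) extra <- cbind(extra, scaled[, 2L])
  }
  F <- cbind(code, extra, 1)
  P <- as_row_matrix(softmax_predict(object$theta, F))
  if (type == "prob") {
    colnames(P) <- object$class_names
    P
  } else {
    apply(P, 1L, which.max) - 1L
  }
}

#' Save / load a trained model
#'
#' Portable plain-text persistence: every weight array is stored at full
#' precision in a JSON container, so a reload reproduces the model
#' bit-exactly.
#'
#' @param model a `rhythm_classifier`.
#' @param path output file.
#' @return `save_model`: `path` invisibly; `load_model`: the restored
#'   `rhythm_classifier`.
#' @export
save_model <- function(model, path) {
  ser <- function(x) list(dim = dim(x) %||% length(x),
                          data = sprintf("%.17g", as.numeric(x)))
  obj <- list(
    layer1 = lapply(model$stack$layer1[c("W1", "b1", "W2", "b2")], ser),
    layer2 = lapply(model$stack$layer2[c("W1", "b1", "W2", "b2")], ser),
    sizes = list(l1 = c(model$stack$layer1$n_visible, model$stack$layer1$n_hidden),
                 l2 = c(model$stack$layer2$n_visible, model$stack$layer2$n_hidden)),
    theta = ser(model$theta),
    scaler = model$scaler[c("method", "min", "max", "mean", "sd")],
    include_cov = model$include_cov, include_apen = model$include_apen,
    class_names = model$class_names,
    config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  des <- function(s) {
    v <- as.numeric(s$data)
    if (length(s$dim) == 2L) matrix(v, s$dim[1], s$dim[2]) else v
  }
  mk_layer <- function(l, sizes) {
    w <- lapply(l, des)
    w$n_visible <- sizes[1]; w$n_hidden <- sizes[2]
    w
  }
  stack <- structure(list(layer1 = mk_layer(obj$layer1, obj$sizes$l1),
                          layer2 = mk_layer(obj$layer2, obj$sizes$l2),
                          config = NULL),
                     class = "sae_stack")
  scaler <- structure(c(obj$scaler, list(fitted = TRUE)), class = "feature_scaler")
  cfg <- obj$config
  config <- sae_config(layer_sizes = cfg$layer_sizes, l2_weight = cfg$l2_weight,
                       sparsity_weight = cfg$sparsity_weight,
                       sparsity_target = cfg$sparsity_target,
                       unsup_epochs = cfg$unsup_epochs, sup_epochs = cfg$sup_epochs,
                       optimizer = cfg$optimizer, lr = cfg$lr,
                       fine_tune_scope = cfg$fine_tune_scope)
  stack$config <- config
  structure(list(stack = stack, theta = des(obj$theta), scaler = scaler,
                 include_cov = obj$include_cov, include_apen = obj$include_apen,
                 trajectory = NULL, class_names = obj$class_names,
                 config = config),
            class = "rhythm_classifier")
}
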