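#' Approximate entropy of a sequence
#'
#' Pincus' ApEn(m, r): `Phi_m(r) - Phi_{m+1}(r)`, where `Phi_m` is the
#' mean natural-log fraction of length-`m` templates within Chebyshev
#' distance `r` of each template, with self-matches included. ApEn is 0
#' for a perfectly regular (constant) sequence and grows with the
#' complexity/randomness of the series. With `r` specified as a fraction
#' of the sample SD (the default `0.2 * sd(x)`), ApEn is invariant to
#' affine rescaling of `x`.
#'
#' @param x numeric sequence, length `> m + 1`.
#' @param m embedding (template) dimension, default 2.
#' @param r tolerance radius; default `0.2 * sd(x)` (floored at a tiny
#'   positive value when `sd(x) = 0`).
#' @return non-negative scalar.
#' @examples
#' approximate_entropy(rep(1, 50))            # 0
#' approximate_entropy(sin(1:200), m = 2)
#' @export
approximate_entropy <- function(x, m = 2L, r = NULL) {
  x <- as.numeric(x)
  N <- length(x)
  if (N <= m + 1L) {
    stop(sprintf("sequence too short for ApEn: need length > %d, got %d", m + 1L, N),
         call. = FALSE)
  }
  if (is.null(r)) {
    s <- stats::sd(x)
    r <- if (s > 0) 0.2 * s else 1e-12
  }
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  # pairwise |x_i - x_j| once; Chebyshev template distance is a running max
  D <- abs(outer(x, x, "-"))
  phi <- function(mm) {
    nw <- N - mm + 1L
    DM <- D[seq_len(nw), seq_len(nw), drop = FALSE]
    if (mm > 1L) {
      for (k in seq_len(mm - 1L)) {
        DM <- pmax(DM, D[k + seq_len(nw), k + seq_len(nw), drop = FALSE])
      }
    }
    mean(log(rowSums(DM <= r) / nw))
  }
  phi(m) - phi(m + 1L)
}

#' Dispersion feature of an ISI sequence
#'
#' The dispersion statistic fused with the learned code. Default mode is
#' the coefficient of variation `sd(x)/mean(x)`, the standard ISI
#' dispersion index; `"lag1_autocov"` (mean of lag-1 products of centred
#' values) is provided as an alternative reading of a single-series
#' "covariance".
#'
#' @param x numeric sequence, length >= 2.
#' @param mode `"cv"` (default) or `"lag1_autocov"`.
#' @param sd_type `"sample"` (default, divisor `n - 1`) or `"population"`.
#' @return scalar.
#' @examples
#' dispersion_feature(c(2, 4, 6, 8))              # sd/mean
#' dispersion_feature(c(2, 4, 6, 8), "lag1_autocov")
#' @export
dispersion_feature <- function(x, mode = c("cv", "lag1_autocov"),
                               sd_type = c("sample", "population")) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (mode == "cv") {
    mu <- mean(x)
    if (mu == 0) stop("cv undefined: mean is zero", call. = FALSE)
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((n - 1) / n)
    s / mu
  } else {
    xc <- x - mean(x)
    mean(xc[-n] * xc[-1L])
  }
}

#' Compute the two hand-crafted features for every row of a matrix
#'
#' @param X numeric matrix, rows = sequences (normally the normalized
#'   1024-wide vectors).
#' @param m,r_frac ApEn embedding dimension and tolerance as a fraction
#'   of each row's SD.
#' @param cov_mode dispersion mode, see [dispersion_feature()].
#' @return data.frame with columns `cov` and `apen`, one row per input row.
#' @export
compute_features <- function(X, m = 2L, r_frac = 0.2,
                             cov_mode = c("cv", "lag1_autocov")) {
  cov_mode <- match.arg(cov_mode)
  X <- as_row_matrix(X)
  cov <- apply(X, 1L, function(x) {
    if (mean(x) == 0) 0 else dispersion_feature(x, mode = cov_mode)
  })
  apen <- apply(X, 1L, function(x) {
    s <- stats::sd(x)
    approximate_entropy(x, m = m, r = if (s > 0) r_frac * s else 1e-12)
  })
  data.frame(cov = cov, apen = apen)
}

#' Fit / apply a feature scaler
#'
#' `fit_scaler` learns per-column scaling parameters on training features
#' only; `apply_scaler` maps new features with the frozen parameters.
#' Methods: `"minmax"` (default; maps the training range to \[0, 1\],
#' constant columns to 0), `"zscore"`, `"none"`.
#'
#' @param X numeric matrix or data.frame of scalar features.
#' @param method scaling method.
#' @return `fit_scaler`: object of class `feature_scaler`;
#'   `apply_scaler`: scaled numeric matrix.
#' @export
fit_scaler <- function(X, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  structure(list(method = method,
                 min = apply(X, 2L, min), max = apply(X, 2L, max),
                 mean = colMeans(X), sd = apply(X, 2L, stats::sd),
                 fitted = TRUE),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @export
apply_scaler <- function(X, scaler) {
  if (!inherits(scaler, "feature_scaler") || !isTRUE(scaler$fitted)) {
    stop("scaler not fitted", call. = FALSE)
  }
  X <- as.matrix(X)
  if (scaler$method == "none") return(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    if (scaler$method == "minmax") {
      rng <- scaler$max[j] - scaler$min[j]
      out[, j] <- if (rng == 0) 0 else (X[, j] - scaler$min[j]) / rng
    } else {
      out[, j] <- if (scaler$sd[j] == 0) 0 else (X[, j] - scaler$mean[j]) / scaler$sd[j]
    }
  }
  out
}

#' Fuse the learned code with the hand-crafted scalar features
#'
#' Concatenates each row's auto-encoder code with its (scaled) dispersion
#' and/or ApEn scalars, in that order. With the default 824-wide code and
#' both scalars the fused vector has length 826; the four ablation
#' configurations (code-only, +cov, +apen, +both) give widths 824, 825,
#' 825, 826.
#'
#' @param code numeric matrix of learned codes (rows = sequences) or a
#'   single code vector.
#' @param features data.frame from [compute_features()] (columns `cov`,
#'   `apen`), or `NULL` when neither scalar is used.
#' @param scaler fitted `feature_scaler` for the scalars (required unless
#'   both `include_*` flags are `FALSE`).
#' @param include_cov,include_apen which scalars to append.
#' @return numeric matrix of fused feature rows.
#' @export
fuse_features <- function(code, features = NULL, scaler = NULL,
                          include_cov = TRUE, include_apen = TRUE) {
  code <- as_row_matrix(code)
  if (!include_cov && !include_apen) return(code)
  if (is.null(features)) stop("features required when a scalar is fused", call. = FALSE)
  if (is.null(scaler)) stop("scaler not fitted", call. = FALSE)
  scaled <- apply_scaler(as.matrix(features[, c("cov", "apen"), drop = FALSE]), scaler)
  extra <- NULL
  if (include_cov) extra <- cbind(extra, scaled[, 1L])
  if (include_apen) extra <- cbind(extra, scaled[, 2L])
  cbind(code, extra, deparse.level = 0)
}
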