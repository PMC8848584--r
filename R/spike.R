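#' Detect spikes in a membrane trace
#'
#' A spike is an upward crossing of `threshold` followed by a local
#' maximum of `V`; the spike time is the time of that maximum. Crossings
#' falling inside the refractory window of the previous accepted spike are
#' suppressed.
#'
#' @param trace a `membrane_trace`.
#' @param threshold crossing threshold (mV); default 0.
#' @param refractory minimum time between consecutive spikes (model time
#'   units); default 2.
#' @return object of class `spike_train`: list with `times` (strictly
#'   increasing, possibly empty) and `source_meta`.
#' @examples
#' tr <- simulate_chay(chay_params(), chay_state(), dt = 0.01, T = 5)
#' detect_spikes(tr, threshold = -20, refractory = 0.05)
#' @export
detect_spikes <- function(trace, threshold = 0, refractory = 2) {
  V <- trace$V
  tt <- trace$t
  nlen <- length(V)
  if (nlen == 0L) stop("trace is empty", call. = FALSE)
  up <- which(V[-1L] >= threshold & V[-nlen] < threshold)
  times <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (tt[i + 1L] - last < refractory) next
    j <- i + 1L
    while (j < nlen && V[j + 1L] > V[j]) j <- j + 1L
    if (tt[j] - last < refractory) next
    times <- c(times, tt[j])
    last <- tt[j]
  }
  structure(list(times = times, source_meta = trace$meta),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes", length(x$times)))
  if (length(x$times) >= 2) {
    cat(sprintf(", mean ISI %.4g", mean(diff(x$times))))
  }
  cat("\n")
  invisible(x)
}

#' Extract interspike intervals from a spike train
#'
#' @param train a `spike_train` (or bare numeric vector of spike times).
#' @param label optional integer class label in `0:3`.
#' @return object of class `isi_sequence`: list with `values` (positive
#'   intervals), `label`, and `normalized = FALSE`.
#' @examples
#' extract_isi(c(0, 1, 3, 6))$values  # 1 2 3
#' @export
extract_isi <- function(train, label = NULL) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (length(times) < 2L) stop("insufficient spikes: need at least 2", call. = FALSE)
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(values = diff(times), label = label, normalized = FALSE),
            class = "isi_sequence")
}

#' Truncate and normalize an ISI sequence
#'
#' Keeps the first `target_len` intervals and rescales them per sequence.
#' The default min-max scaling maps the sequence into \[0, 1\] (the input
#' range of the logistic auto-encoder); a constant sequence maps to all
#' zeros (guarded division). `"zscore"` centring/scaling is available as
#' an alternative (its output is not range-bounded).
#'
#' @param seq an `isi_sequence` or numeric vector of intervals.
#' @param target_len required output length (default 1024).
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return numeric vector of length `target_len`.
#' @examples
#' preprocess_isi(c(2, 4, 6, 8), target_len = 4)  # 0 1/3 2/3 1
#' @export
preprocess_isi <- function(seq, target_len = 1024L, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  x <- if (inherits(seq, "isi_sequence")) seq$values else as.numeric(seq)
  if (length(x) < target_len) {
    stop(sprintf("sequence too short: preprocessing requires at least %d intervals, got %d",
                 target_len, length(x)), call. = FALSE)
  }
  x <- x[seq_len(target_len)]
  if (method == "minmax") {
    rng <- max(x) - min(x)
    if (rng == 0) return(rep(0, target_len))
    (x - min(x)) / rng
  } else {
    s <- stats::sd(x)
    if (s == 0) return(rep(0, target_len))
    (x - mean(x)) / s
  }
}

# Simulate one model configuration until at least `n_spikes` spikes are
# collected, extending the run up to max_T; returns raw ISI values.
simulate_isi_sequence <- function(params, init, n_spikes, dt, chunk_T, max_T,
                                  noise = NULL, method = "euler",
                                  threshold = 0, refractory = 0.05) {
  elapsed <- 0
  state <- init
  all_times <- numeric(0)
  t_offset <- 0
  while (elapsed < max_T) {
    tr <- if (is.null(noise)) {
      simulate_chay(params, state, dt = dt, T = chunk_T, method = method)
    } else {
      simulate_chay_stochastic(params, state, noise = noise, dt = dt, T = chunk_T)
    }
    st <- detect_spikes(tr, threshold = threshold, refractory = refractory)
    all_times <- c(all_times, st$times + t_offset)
    m <- length(tr$t)
    state <- chay_state(tr$V[m], min(max(tr$n[m], 0), 1), max(tr$C[m], 0))
    t_offset <- t_offset + tr$t[m]
    elapsed <- elapsed + chunk_T
    # keep stochastic chunks independent but reproducible
    if (!is.null(noise) && !is.null(noise$seed)) noise$seed <- noise$seed + 1L
    if (length(all_times) >= n_spikes) break
  }
  # de-duplicate spikes straddling chunk joints (refractory across chunks)
  if (length(all_times) >= 2) {
    keep <- c(TRUE, diff(all_times) >= refractory)
    all_times <- all_times[keep]
  }
  if (length(all_times) < n_spikes) return(NULL)
  diff(all_times[seq_len(n_spikes)])
}
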