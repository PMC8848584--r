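# Independent oracles used across the suite. These are deliberately naive
# (double loops, central differences) so they share no code path with the
# package implementations they check.

# Pincus approximate entropy by brute-force double loop, self-matches
# included, Chebyshev distance, natural log.
apen_bruteforce <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nw <- N - mm + 1L
    logc <- numeric(nw)
    for (i in seq_len(nw)) {
      cnt <- 0L
      for (j in seq_len(nw)) {
        d <- max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      logc[i] <- log(cnt / nw)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1L)
}

# Central finite-difference gradient of fn(theta)$cost.
fd_gradient <- function(fn, theta, eps = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    g[i] <- (fn(tp)$cost - fn(tm)$cost) / (2 * eps)
  }
  g
}

rel_grad_err <- function(analytic, numeric) {
  max(abs(analytic - numeric)) / max(abs(analytic), 1e-8)
}

# Synthetic membrane trace of identical triangular pulses at given peak
# times, riding on a flat baseline.
triangle_trace <- function(peak_times, baseline = -60, peak = 20,
                           half_width = 0.1, dt = 0.01, T = NULL) {
  if (is.null(T)) T <- max(peak_times) + 1
  t <- seq(0, T, by = dt)
  V <- rep(baseline, length(t))
  for (pt in peak_times) {
    w <- abs(t - pt) <= half_width
    V[w] <- pmax(V[w], baseline + (peak - baseline) * (1 - abs(t[w] - pt) / half_width))
  }
  spikesae:::new_membrane_trace(t, V, meta = list(synthetic = "triangular pulses"))
}

# Trivially separable toy dataset shaped like an isi_dataset: four
# structured class prototypes in [0,1]^width plus noise that is small
# relative to each prototype's own variability, so the scalar features
# (ApEn, CV) are stable within a class, not just the raw vectors.
make_toy_dataset <- function(n_train = 6L, n_test = 3L, width = 32L, seed = 1L,
                             noise_sd = 0.01) {
  set.seed(seed)
  i <- seq_len(width)
  protos <- rbind(0.5 + 0.4 * sin(2 * pi * i / 16),
                  rep(c(0.2, 0.8), length.out = width),
                  seq(0.05, 0.95, length.out = width),
                  rep(c(0.1, 0.1, 0.9, 0.9), length.out = width))
  mk <- function(n_per) {
    x <- NULL; y <- integer(0)
    for (cls in 0:3) {
      block <- matrix(rep(protos[cls + 1L, ], n_per), nrow = n_per, byrow = TRUE) +
        matrix(rnorm(n_per * width, 0, noise_sd), n_per)
      x <- rbind(x, pmin(pmax(block, 0), 1))
      y <- c(y, rep.int(cls, n_per))
    }
    list(x = x, y = y)
  }
  tr <- mk(n_train); te <- mk(n_test)
  structure(list(train = tr$x, train_labels = tr$y,
                 test = te$x, test_labels = te$y,
                 class_names = rhythm_classes(),
                 provenance = list(mode = "toy", seed = seed)),
            class = "isi_dataset")
}
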