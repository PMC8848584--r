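#' Class names of the four discharge rhythms
#'
#' Labels 0-3 map to periodic discharge (PD), random discharge alternating
#' with two periodic cluster discharges (RD), chaotic discharge (CD) and
#' integer-multiple discharge (IMD).
#'
#' @return character vector of length 4.
#' @export
rhythm_classes <- function() c("PD", "RD", "CD", "IMD")

#' Generate archetypal raw ISI sequences for one rhythm class
#'
#' Statistical surrogates that reproduce the phenomenology of each rhythm
#' without running the ion-channel model:
#' \describe{
#'   \item{PD (0)}{near-constant ISIs: base period with a slow sinusoidal
#'     period drift plus much smaller i.i.d. jitter, total CV about the
#'     `jitter` parameter (default 0.01). `jitter = 0` gives an exactly
#'     constant sequence.}
#'   \item{RD (1)}{random alternation between two periodic cluster motifs
#'     (short and long period) with geometrically distributed run
#'     lengths.}
#'   \item{CD (2)}{ISIs driven by the logistic map at a chaotic parameter
#'     value, affinely rescaled into a positive interval.}
#'   \item{IMD (3)}{base period times an integer drawn from a shifted
#'     geometric distribution, plus jitter small enough that each ISI
#'     divided by the base period still rounds to that integer.}
#' }
#'
#' @param class_id integer in `0:3`.
#' @param n_seqs number of sequences.
#' @param length intervals per sequence (default 1024).
#' @param seed optional RNG seed.
#' @param params named list of overrides: `base_period` (default 1),
#'   `jitter` (PD, default 0.01), `rd_periods` (RD, default
#'   `c(0.6, 1.6)`), `rd_mean_run` (default 6), `cd_r` (logistic map
#'   parameter, default 3.9), `cd_range` (default `c(0.4, 1.6)`),
#'   `imd_p` (geometric success prob., default 0.55), `imd_jitter_sd`
#'   (default 0.02).
#' @return matrix `n_seqs x length` of raw (unnormalized) positive ISIs.
#' @examples
#' x <- generate_archetype(3, n_seqs = 2, length = 64, seed = 1)
#' all(abs(x - round(x)) < 0.5)  # integer-multiple structure
#' @export
generate_archetype <- function(class_id, n_seqs, length = 1024L, seed = NULL,
                               params = list()) {
  if (!class_id %in% 0:3) stop(sprintf("unknown class_id: %s", class_id), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(
    list(base_period = 1, jitter = 0.01, rd_periods = c(0.6, 1.6),
         rd_mean_run = 6, cd_r = 3.9, cd_range = c(0.4, 1.6),
         imd_p = 0.55, imd_jitter_sd = 0.02),
    params)
  out <- matrix(0, nrow = n_seqs, ncol = length)
  for (s in seq_len(n_seqs)) {
    out[s, ] <- switch(as.character(class_id),
      "0" = archetype_pd(length, p),
      "1" = archetype_rd(length, p),
      "2" = archetype_cd(length, p),
      "3" = archetype_imd(length, p))
  }
  out
}

# PD: slow sinusoidal period drift dominates a much smaller iid jitter,
# so the sequence stays regular at the ApEn radius (0.2 sd).
# drift sd = 1.39*j/sqrt(2) ~ 0.98 j; noise sd = 0.05 j; total CV ~ j.
archetype_pd <- function(len, p) {
  j <- p$jitter
  if (j == 0) return(rep(p$base_period, len))
  period <- stats::runif(1, 80, 120)
  phase <- stats::runif(1, 0, 2 * pi)
  drift <- 1.39 * j * sin(2 * pi * seq_len(len) / period + phase)
  noise <- stats::rnorm(len, 0, 0.05 * j)
  p$base_period * (1 + drift + noise)
}

# RD: alternating cluster motifs with geometric run lengths.
archetype_rd <- function(len, p) {
  out <- numeric(0)
  motif <- sample(1:2, 1)
  while (length(out) < len) {
    run <- 2L + stats::rgeom(1, 1 / p$rd_mean_run)
    per <- p$base_period * p$rd_periods[motif]
    out <- c(out, per * (1 + stats::rnorm(run, 0, 0.02)))
    motif <- 3L - motif
  }
  pmax(out[seq_len(len)], 1e-6)
}

# CD: logistic map at a chaotic parameter, rescaled to a positive range.
archetype_cd <- function(len, p) {
  x <- stats::runif(1, 0.2, 0.8)
  for (i in 1:100) x <- p$cd_r * x * (1 - x)  # burn-in
  out <- numeric(len)
  for (i in seq_len(len)) {
    x <- p$cd_r * x * (1 - x)
    out[i] <- x
  }
  p$base_period * (p$cd_range[1] + diff(p$cd_range) * out)
}

# IMD: base period times a shifted-geometric integer, small jitter.
archetype_imd <- function(len, p) {
  k <- 1L + stats::rgeom(len, p$imd_p)
  p$base_period * (k + stats::rnorm(len, 0, p$imd_jitter_sd))
}

#' Default Chay-model regime per rhythm class
#'
#' The class-to-model mapping used by `build_dataset(mode = "chay")`,
#' fixed by a numerical scan over the calcium-gated K+ conductance
#' `g_KC` (the bifurcation parameter along which the model moves from
#' tonic spiking through period-adding bursting and chaos to slow-wave
#' quiescence):
#' \describe{
#'   \item{PD}{deterministic tonic (period-1) regime, `g_KC = 10.5`; ISI
#'     coefficient of variation below 0.01.}
#'   \item{RD}{improved deterministic model (`w_K = 1.02`) at
#'     `g_KC = 11.2`: aperiodic alternation between multi-spike clusters
#'     and single/double discharges, with no noise.}
#'   \item{CD}{deterministic chaotic regime, `g_KC = 11.0` (irregular
#'     burst-length sequence).}
#'   \item{IMD}{K+ channel noise (`N_K = 10000`) at `g_KC = 27.2`, just
#'     past the firing-failure boundary: noise decides whether each
#'     slow-wave cycle fires, so ISIs cluster at integer multiples of
#'     the cycle period.}
#' }
#' Deterministic regimes integrate with RK4 at `dt = 0.001`; the
#' stochastic regime with Euler-Maruyama at `dt = 0.002`. Spikes are
#' detected at -25 mV (the spike peaks of this parameterization sit
#' near -16 mV). Every entry can be overridden wholesale through
#' `build_dataset`'s `config$regimes`.
#'
#' @return named list (`PD`, `RD`, `CD`, `IMD`) of regime specifications
#'   (components `params`, `init`, `dt`, `chunk_T`, `threshold`,
#'   `refractory`, `method`, `noise`).
#' @export
chay_regimes <- function() {
  init <- chay_state(-40, 0.4, 0.5)
  base <- list(init = init, dt = 0.001, chunk_T = 100, threshold = -25,
               refractory = 0.05, method = "rk4", noise = NULL)
  list(
    PD = utils::modifyList(base, list(params = chay_params(g_KC = 10.5))),
    RD = utils::modifyList(base, list(params = chay_params(g_KC = 11.2, w_K = 1.02))),
    CD = utils::modifyList(base, list(params = chay_params(g_KC = 11.0))),
    IMD = utils::modifyList(base, list(
      params = chay_params(g_KC = 27.2), dt = 0.002,
      noise = noise_spec("k_white", D = 1, N_K = 10000)))
  )
}

#' Build the labeled four-rhythm ISI dataset
#'
#' Emits the standard study-shaped dataset: per class, `n_train + n_test`
#' sequences (default 40 + 20) of `length` normalized ISIs (default
#' 1024), labels 0-3 mapped to PD/RD/CD/IMD. `"archetype"` mode uses the
#' statistical surrogates of [generate_archetype()]; `"chay"` mode
#' simulates each class's regime ([chay_regimes()]) until at least
#' `length + 1` spikes are collected, then truncates and normalizes.
#'
#' @param config named list of overrides: `n_train`, `n_test`, `length`,
#'   `archetype_params` (per-class list passed to [generate_archetype()]),
#'   `regimes` (per-class list as in [chay_regimes()]), `max_T` (chay-mode
#'   simulation time budget per sequence, default 5000).
#' @param seed RNG seed; the build is deterministic given the seed.
#' @param mode `"archetype"` (fast surrogates) or `"chay"` (mechanistic).
#' @return object of class `isi_dataset`: list with `train` and `test`
#'   numeric matrices (rows = sequences, values in \[0, 1\]),
#'   `train_labels`/`test_labels` (integers 0-3), `class_names`, and
#'   `provenance` (mode, seed, config).
#' @examples
#' ds <- build_dataset(config = list(n_train = 4, n_test = 2, length = 64),
#'                     seed = 1)
#' dim(ds$train)  # 16 x 64
#' @export
build_dataset <- function(config = list(), seed = 0,
                          mode = c("archetype", "chay")) {
  mode <- match.arg(mode)
  cfg <- utils::modifyList(
    list(n_train = 40L, n_test = 20L, length = 1024L,
         archetype_params = list(), regimes = NULL, max_T = 5000),
    config)
  classes <- rhythm_classes()
  n_per <- cfg$n_train + cfg$n_test
  train <- NULL; test <- NULL
  train_labels <- integer(0); test_labels <- integer(0)
  for (cls in 0:3) {
    if (mode == "archetype") {
      raw <- generate_archetype(cls, n_per, length = cfg$length,
                                seed = derive_seed(seed, cls),
                                params = cfg$archetype_params)
    } else {
      regimes <- if (is.null(cfg$regimes)) chay_regimes() else cfg$regimes
      rg <- regimes[[classes[cls + 1L]]]
      raw <- matrix(0, nrow = n_per, ncol = cfg$length)
      for (s in seq_len(n_per)) {
        noise <- rg$noise
        if (!is.null(noise)) noise$seed <- derive_seed(seed, cls * 100L + s)
        isi <- simulate_isi_sequence(rg$params, rg$init,
                                     n_spikes = cfg$length + 1L,
                                     dt = rg$dt, chunk_T = rg$chunk_T,
                                     max_T = cfg$max_T, noise = noise,
                                     method = rg$method,
                                     threshold = rg$threshold,
                                     refractory = rg$refractory)
        if (is.null(isi)) {
          stop(sprintf("class %s: fewer than %d spikes within the time budget (max_T = %g)",
                       classes[cls + 1L], cfg$length + 1L, cfg$max_T), call. = FALSE)
        }
        raw[s, ] <- isi
      }
    }
    norm <- t(apply(raw, 1L, preprocess_isi, target_len = cfg$length))
    train <- rbind(train, norm[seq_len(cfg$n_train), , drop = FALSE])
    test <- rbind(test, norm[cfg$n_train + seq_len(cfg$n_test), , drop = FALSE])
    train_labels <- c(train_labels, rep.int(cls, cfg$n_train))
    test_labels <- c(test_labels, rep.int(cls, cfg$n_test))
  }
  structure(list(train = train, train_labels = train_labels,
                 test = test, test_labels = test_labels,
                 class_names = classes,
                 provenance = list(mode = mode, seed = seed, config = cfg)),
            class = "isi_dataset")
}

#' @export
print.isi_dataset <- function(x, ...) {
  cat(sprintf("isi_dataset: %d train / %d test sequences of length %d (%s mode)\n",
              nrow(x$train), nrow(x$test), ncol(x$train),
              x$provenance$mode))
  cat("classes:", paste(sprintf("%s=%d", x$class_names, 0:3), collapse = ", "), "\n")
  invisible(x)
}

#' Read one ISI dataset CSV file
#'
#' Expects one sequence per row: `expected_length` numeric value columns
#' followed by an integer `label` column in `0:3`. Files with or without
#' a header line are both accepted.
#'
#' @param path CSV file.
#' @param expected_length required number of value columns (default 1024).
#' @return list with `x` (numeric matrix) and `labels` (integer vector).
#' @export
read_isi_file <- function(path, expected_length = 1024L) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) != expected_length + 1L) {
    stop(sprintf("malformed dataset file: expected %d value columns plus a label column, found %d columns",
                 expected_length, ncol(df)), call. = FALSE)
  }
  x <- as.matrix(df[, seq_len(expected_length), drop = FALSE])
  labels <- df[[expected_length + 1L]]
  bad <- which(!is.finite(as.numeric(labels)) | labels != floor(labels) |
                 labels < 0 | labels > 3)
  if (length(bad) > 0) {
    stop(sprintf("row %d: label %s outside {0,1,2,3}", bad[1], labels[bad[1]]),
         call. = FALSE)
  }
  nonnum <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(nonnum) > 0) {
    stop(sprintf("row %d: non-numeric or missing ISI value", nonnum[1, 1]),
         call. = FALSE)
  }
  dimnames(x) <- NULL
  list(x = x, labels = as.integer(labels))
}

#' Write / read a labeled dataset directory
#'
#' `write_dataset` writes `train.csv`, `test.csv` (value columns then a
#' `label` column) and `provenance.json` into `dir`; `read_dataset`
#' reads the pair back into an `isi_dataset`. Numeric values and labels
#' round-trip exactly (values are written at full precision).
#'
#' @param ds an `isi_dataset`.
#' @param dir directory (created if missing).
#' @return `write_dataset`: `dir` invisibly. `read_dataset`: an
#'   `isi_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_half <- function(x, labels, path) {
    df <- as.data.frame(x)
    names(df) <- sprintf("v%d", seq_len(ncol(x)))
    df$label <- labels
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  write_half(ds$train, ds$train_labels, file.path(dir, "train.csv"))
  write_half(ds$test, ds$test_labels, file.path(dir, "test.csv"))
  prov <- ds$provenance
  prov$config$regimes <- NULL # nested closures/objects; shape fields suffice
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param expected_length required sequence length (default 1024).
#' @export
read_dataset <- function(dir, expected_length = 1024L) {
  tr <- read_isi_file(file.path(dir, "train.csv"), expected_length)
  te <- read_isi_file(file.path(dir, "test.csv"), expected_length)
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()
  structure(list(train = tr$x, train_labels = tr$labels,
                 test = te$x, test_labels = te$labels,
                 class_names = rhythm_classes(), provenance = prov),
            class = "isi_dataset")
}
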