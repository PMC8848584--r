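#' Parameters of the Chay neuron model
#'
#' The Chay model is a three-variable ion-channel model of an excitable
#' cell: membrane potential `V`, potassium activation probability `n`, and
#' dimensionless intracellular free calcium `C`. Membrane currents are a
#' mixed Na+/Ca2+ inward current gated by instantaneous `m_inf^3 h_inf`, a
#' voltage-gated K+ current gated by `n^4`, a calcium-gated K+ current with
#' activation `C/(1+C)`, and a leak. The defaults are the canonical
#' parameter set of Chay's original three-variable model; every value can
#' be overridden.
#'
#' @param g_I mixed Na+/Ca2+ conductance (model units, /s).
#' @param g_KV voltage-gated K+ conductance.
#' @param g_KC calcium-gated K+ conductance.
#' @param g_L leak conductance.
#' @param V_I,V_K,V_L,V_C reversal potentials (mV) of the mixed, K+, leak
#'   currents and of the calcium flux driving term.
#' @param K_C calcium efflux rate constant.
#' @param rho scale of the calcium kinetics.
#' @param lambda_n rate scale of the K+ gating variable (enters `tau_n`).
#' @param w_K K+-channel opening control parameter of the improved
#'   deterministic variant; `w_K = 1` recovers the original gating
#'   equation, `w_K > 1` speeds K+ channel opening, mimicking the
#'   near-instantaneous opening at the action-potential peak.
#' @return object of class `chay_params` (a named list).
#' @examples
#' p <- chay_params()                 # canonical set
#' p2 <- chay_params(w_K = 2.2)       # improved-model variant
#' @export
chay_params <- function(g_I = 1800, g_KV = 1700, g_KC = 12, g_L = 7,
                        V_I = 100, V_K = -75, V_L = -40, V_C = 100,
                        K_C = 3.3 / 18, rho = 0.27, lambda_n = 230,
                        w_K = 1) {
  p <- list(g_I = g_I, g_KV = g_KV, g_KC = g_KC, g_L = g_L,
            V_I = V_I, V_K = V_K, V_L = V_L, V_C = V_C,
            K_C = K_C, rho = rho, lambda_n = lambda_n, w_K = w_K)
  for (nm in c("g_I", "g_KV", "g_KC", "g_L")) {
    if (p[[nm]] < 0) stop(sprintf("conductance %s must be >= 0", nm), call. = FALSE)
  }
  if (p$rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (p$w_K <= 0) stop("w_K must be > 0", call. = FALSE)
  structure(p, class = "chay_params")
}

#' State of the Chay model
#'
#' @param V membrane potential (mV).
#' @param n K+ channel open probability, in \[0, 1\].
#' @param C intracellular free calcium (dimensionless, >= 0).
#' @return object of class `chay_state` (named numeric vector).
#' @export
chay_state <- function(V = -40, n = 0.4, C = 0.5) {
  if (n < 0 || n > 1) stop("n must lie in [0, 1]", call. = FALSE)
  if (C < 0) stop("C must be >= 0", call. = FALSE)
  structure(c(V = V, n = n, C = C), class = "chay_state")
}

#' Steady-state gating functions of the Chay model
#'
#' Hodgkin-Huxley-style rate functions with Chay's voltage shifts. The two
#' removable singularities (at `V = -25` and `V = -20` mV) are filled with
#' their analytic limits.
#'
#' @param V membrane potential (mV), scalar or vector.
#' @param lambda_n rate scale of the K+ gating variable.
#' @return list with components `m_inf`, `h_inf`, `n_inf`, `tau_n`.
#' @export
chay_gating <- function(V, lambda_n = 230) {
  am_x <- V + 25
  alpha_m <- ifelse(abs(am_x) < 1e-7, 1, 0.1 * am_x / (1 - exp(-am_x / 10)))
  beta_m <- 4 * exp(-(V + 50) / 18)
  alpha_h <- 0.07 * exp(-(V + 50) / 20)
  beta_h <- 1 / (1 + exp(-(V + 20) / 10))
  an_x <- V + 20
  alpha_n <- ifelse(abs(an_x) < 1e-7, 0.1, 0.01 * an_x / (1 - exp(-an_x / 10)))
  beta_n <- 0.125 * exp(-(V + 30) / 80)
  list(m_inf = alpha_m / (alpha_m + beta_m),
       h_inf = alpha_h / (alpha_h + beta_h),
       n_inf = alpha_n / (alpha_n + beta_n),
       tau_n = 1 / (lambda_n * (alpha_n + beta_n)))
}

#' Time derivatives of the Chay model
#'
#' Evaluates the vector field of the (possibly improved) deterministic Chay
#' model. With `w_K = 1` in `params` the gating equation is the original
#' first-order relaxation `(n_inf - n)/tau_n`; for other `w_K` the
#' relaxation is scaled by `w_K`.
#'
#' @param state `chay_state` or named numeric vector with `V`, `n`, `C`.
#' @param params `chay_params`.
#' @return named numeric vector `c(dV, dn, dC)` (per model time unit).
#' @examples
#' chay_derivatives(chay_state(-40, 0.4, 0.5), chay_params())
#' @export
chay_derivatives <- function(state, params) {
  V <- unname(state[["V"]]); n <- unname(state[["n"]]); C <- unname(state[["C"]])
  for (nm in c("V", "n", "C")) {
    if (!is.finite(state[[nm]])) {
      stop(sprintf("non-finite state component: %s", nm), call. = FALSE)
    }
  }
  d <- chay_rhs(V, n, C, params)
  c(dV = d[1], dn = d[2], dC = d[3])
}

# Internal vector field; V, n, C scalars, p a chay_params list.
chay_rhs <- function(V, n, C, p) {
  g <- chay_gating(V, p$lambda_n)
  mh <- g$m_inf^3 * g$h_inf
  dV <- p$g_I * mh * (p$V_I - V) +
    p$g_KV * n^4 * (p$V_K - V) +
    p$g_KC * C / (1 + C) * (p$V_K - V) +
    p$g_L * (p$V_L - V)
  dn <- p$w_K * (g$n_inf - n) / g$tau_n
  dC <- p$rho * (mh * (p$V_C - V) - p$K_C * C)
  c(dV, dn, dC)
}

new_membrane_trace <- function(t, V, n = NULL, C = NULL, meta = list()) {
  structure(list(t = t, V = V, n = n, C = C, meta = meta),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("membrane_trace: %d samples, t in [%g, %g], V in [%.2f, %.2f] mV\n",
              length(x$t), x$t[1], x$t[length(x$t)], min(x$V), max(x$V)))
  invisible(x)
}

#' @export
plot.membrane_trace <- function(x, ...) {
  graphics::plot(x$t, x$V, type = "l", xlab = "time (model units)",
                 ylab = "V (mV)", ...)
  invisible(x)
}

#' Integrate the deterministic Chay model
#'
#' Fixed-step integration with forward Euler or classical fourth-order
#' Runge-Kutta. The run is fully deterministic: identical inputs give
#' bitwise-identical traces.
#'
#' @param params `chay_params`.
#' @param init `chay_state` initial condition.
#' @param dt time step (model time units, default 0.001).
#' @param T total duration; the trace holds `floor(T/dt) + 1` samples.
#' @param method `"euler"` or `"rk4"`.
#' @param v_guard abort threshold on `|V|` (mV); exceeding it raises an
#'   error naming the time of the blow-up.
#' @return a `membrane_trace` with components `t`, `V`, `n`, `C`, `meta`.
#' @examples
#' tr <- simulate_chay(chay_params(), chay_state(), dt = 0.01, T = 1)
#' range(tr$V)
#' @export
simulate_chay <- function(params, init = chay_state(), dt = 0.001, T = 1,
                          method = c("euler", "rk4"), v_guard = 500) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (T < 0) stop("T must be >= 0", call. = FALSE)
  n_steps <- floor(T / dt + 1e-9)
  nt <- n_steps + 1L
  tv <- numeric(nt); Vv <- numeric(nt); nv <- numeric(nt); Cv <- numeric(nt)
  V <- unname(init[["V"]]); n <- unname(init[["n"]]); C <- unname(init[["C"]])
  tv[1] <- 0; Vv[1] <- V; nv[1] <- n; Cv[1] <- C
  for (i in seq_len(n_steps)) {
    if (method == "euler") {
      d <- chay_rhs(V, n, C, params)
      V <- V + dt * d[1]; n <- n + dt * d[2]; C <- C + dt * d[3]
    } else {
      k1 <- chay_rhs(V, n, C, params)
      k2 <- chay_rhs(V + dt / 2 * k1[1], n + dt / 2 * k1[2], C + dt / 2 * k1[3], params)
      k3 <- chay_rhs(V + dt / 2 * k2[1], n + dt / 2 * k2[2], C + dt / 2 * k2[3], params)
      k4 <- chay_rhs(V + dt * k3[1], n + dt * k3[2], C + dt * k3[3], params)
      V <- V + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      n <- n + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      C <- C + dt / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3])
    }
    if (!is.finite(V) || abs(V) > v_guard) {
      stop(sprintf("integration blow-up at t = %g (|V| > %g)", i * dt, v_guard),
           call. = FALSE)
    }
    tv[i + 1L] <- i * dt; Vv[i + 1L] <- V; nv[i + 1L] <- n; Cv[i + 1L] <- C
  }
  new_membrane_trace(tv, Vv, nv, Cv,
                     meta = list(params = params, init = init, dt = dt, T = T,
                                 method = method, noise = NULL))
}

#' Noise specification for the stochastic Chay variants
#'
#' @param kind one of `"none"`, `"global_white"`, `"global_colored"`,
#'   `"k_white"`, `"k_colored"`. Global kinds perturb the voltage
#'   equation; `k_*` kinds perturb the K+ gating equation with a
#'   channel-number-dependent amplitude.
#' @param D noise intensity (autocorrelation `2 D delta(t - t')` for white
#'   noise; stationary variance `D/tau` for colored noise).
#' @param tau correlation time of the colored (Ornstein-Uhlenbeck) noise.
#' @param N_K number of K+ channels for the channel-noise kinds; the
#'   channel-noise amplitude scales as `1/sqrt(N_K)`.
#' @param seed RNG seed recorded with the trace.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "global_white", "global_colored",
                                "k_white", "k_colored"),
                       D = 0, tau = 1, N_K = 1000, seed = NULL) {
  kind <- match.arg(kind)
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (kind %in% c("global_colored", "k_colored") && tau <= 0) {
    stop("tau must be > 0 for colored noise", call. = FALSE)
  }
  if (kind %in% c("k_white", "k_colored") && N_K < 1) {
    stop("N_K must be >= 1 for channel noise", call. = FALSE)
  }
  structure(list(kind = kind, D = D, tau = tau, N_K = N_K, seed = seed),
            class = "noise_spec")
}

#' Sample a stationary Ornstein-Uhlenbeck (colored noise) path
#'
#' Exact discretization: decay factor `exp(-dt/tau)` with the matching
#' stationary innovation variance, initialized from the stationary law
#' `N(0, D/tau)`. The path has mean 0, variance `D/tau` and
#' autocovariance `(D/tau) exp(-lag/tau)`.
#'
#' @param D noise intensity; `D = 0` yields the all-zero path.
#' @param tau correlation time (> 0).
#' @param dt sampling step.
#' @param n_steps number of samples to return.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n_steps`.
#' @export
sample_ou <- function(D, tau, dt, n_steps, seed = NULL) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (D == 0) return(numeric(n_steps))
  s2 <- D / tau
  a <- exp(-dt / tau)
  innov_sd <- sqrt(s2 * (1 - a * a))
  x <- numeric(n_steps)
  x[1] <- stats::rnorm(1, 0, sqrt(s2))
  z <- stats::rnorm(n_steps - 1, 0, innov_sd)
  for (i in seq_len(n_steps - 1L)) x[i + 1L] <- a * x[i] + z[i]
  x
}

#' Realize the K+ channel-noise term at a fixed state
#'
#' Draws Monte-Carlo samples of the per-step stochastic increment added to
#' the gating equation under channel noise: amplitude
#' `sqrt(2 n (1 - n) / tau_n(V)) / sqrt(N_K)` multiplying Gaussian white
#' noise of intensity `D`. Used to verify the `1/N_K` variance scaling.
#'
#' @param n_samples number of draws.
#' @param V,n membrane potential and gating probability held fixed.
#' @param params `chay_params`.
#' @param D white-noise intensity.
#' @param N_K channel count.
#' @param dt time step (the increment is over one step).
#' @param seed optional RNG seed.
#' @return numeric vector of `n_samples` realized increments.
#' @export
sample_channel_noise <- function(n_samples, V, n, params = chay_params(),
                                 D = 1, N_K = 1000, dt = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- chay_gating(V, params$lambda_n)
  amp <- sqrt(2 * max(n * (1 - n), 0) / g$tau_n) / sqrt(N_K)
  sqrt(2 * D * dt) * amp * stats::rnorm(n_samples)
}

#' Integrate a stochastic Chay model variant
#'
#' Euler-Maruyama integration. Global kinds add their noise to the voltage
#' equation; `k_*` kinds add the channel-noise term to the gating
#' equation. White noise enters with per-step standard deviation
#' `sqrt(2 D dt)`; colored noise is an Ornstein-Uhlenbeck process sampled
#' by exact discretization and added as a drift term. After every step `n`
#' is clamped to \[0, 1\] and `C` floored at 0. With `D = 0` the
#' trajectory is bitwise identical to `simulate_chay(..., method =
#' "euler")`.
#'
#' @inheritParams simulate_chay
#' @param noise `noise_spec`.
#' @return a `membrane_trace`.
#' @examples
#' ns <- noise_spec("global_white", D = 0.5, seed = 1)
#' tr <- simulate_chay_stochastic(chay_params(), chay_state(),
#'                                noise = ns, dt = 0.01, T = 1)
#' @export
simulate_chay_stochastic <- function(params, init = chay_state(),
                                     noise = noise_spec("global_white", D = 1),
                                     dt = 0.001, T = 1, v_guard = 500) {
  if (!inherits(noise, "noise_spec")) stop("noise must be a noise_spec", call. = FALSE)
  if (noise$kind == "none") {
    return(simulate_chay(params, init, dt = dt, T = T, method = "euler",
                         v_guard = v_guard))
  }
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  n_steps <- floor(T / dt + 1e-9)
  nt <- n_steps + 1L
  D <- noise$D
  global <- noise$kind %in% c("global_white", "global_colored")
  colored <- noise$kind %in% c("global_colored", "k_colored")
  # pre-draw the driving noise for the whole run
  if (colored) {
    sig <- if (D > 0) sample_ou(D, noise$tau, dt, n_steps) else numeric(n_steps)
  } else {
    z <- if (D > 0) stats::rnorm(n_steps) else numeric(n_steps)
    white_sd <- sqrt(2 * D * dt)
  }
  inv_sqrt_NK <- 1 / sqrt(noise$N_K)
  tv <- numeric(nt); Vv <- numeric(nt); nv <- numeric(nt); Cv <- numeric(nt)
  V <- unname(init[["V"]]); n <- unname(init[["n"]]); C <- unname(init[["C"]])
  tv[1] <- 0; Vv[1] <- V; nv[1] <- n; Cv[1] <- C
  for (i in seq_len(n_steps)) {
    d <- chay_rhs(V, n, C, params)
    if (global) {
      dW <- if (colored) dt * sig[i] else white_sd * z[i]
      V <- V + dt * d[1] + dW
      n <- n + dt * d[2]
    } else {
      g <- chay_gating(V, params$lambda_n)
      amp <- sqrt(2 * max(n * (1 - n), 0) / g$tau_n) * inv_sqrt_NK
      dW <- if (colored) dt * sig[i] * amp else white_sd * z[i] * amp
      V <- V + dt * d[1]
      n <- n + dt * d[2] + dW
    }
    C <- C + dt * d[3]
    if (n < 0) n <- 0 else if (n > 1) n <- 1
    if (C < 0) C <- 0
    if (!is.finite(V) || abs(V) > v_guard) {
      stop(sprintf("integration blow-up at t = %g (|V| > %g)", i * dt, v_guard),
           call. = FALSE)
    }
    tv[i + 1L] <- i * dt; Vv[i + 1L] <- V; nv[i + 1L] <- n; Cv[i + 1L] <- C
  }
  new_membrane_trace(tv, Vv, nv, Cv,
                     meta = list(params = params, init = init, dt = dt, T = T,
                                 method = "euler_maruyama", noise = noise))
}

#' Export a membrane trace to CSV with a JSON metadata sidecar
#'
#' Writes `t,V,n,C` columns to `path` and the generating configuration to
#' `<path>.json`.
#'
#' @param trace a `membrane_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(t = trace$t, V = trace$V,
                   n = if (is.null(trace$n)) NA else trace$n,
                   C = if (is.null(trace$C)) NA else trace$C)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- trace$meta
  meta$params <- unclass(meta$params)
  meta$init <- as.list(meta$init)
  if (!is.null(meta$noise)) meta$noise <- unclass(meta$noise)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
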