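test_that("gating fixed point: dn/dt vanishes at n = n_inf for any w_K", {
  for (wk in c(1, 2.5)) {
    p <- chay_params(w_K = wk)
    for (V in c(-60, -40, -20)) {
      g <- chay_gating(V, p$lambda_n)
      d <- chay_derivatives(chay_state(V, g$n_inf, 0.5), p)
      expect_equal(unname(d["dn"]), 0, tolerance = 1e-14)
    }
  }
})

test_that("w_K = 1 reduces the improved gating to the original form; w_K scales dn only", {
  s <- chay_state(-35, 0.3, 0.8)
  d1 <- chay_derivatives(s, chay_params(w_K = 1))
  g <- chay_gating(-35, 230)
  # original-form gating assembled independently
  expect_equal(unname(d1["dn"]), (g$n_inf - 0.3) / g$tau_n, tolerance = 1e-12)
  d3 <- chay_derivatives(s, chay_params(w_K = 3))
  expect_equal(unname(d3["dn"]), 3 * unname(d1["dn"]), tolerance = 1e-12)
  expect_equal(unname(d3["dV"]), unname(d1["dV"]))
  expect_equal(unname(d3["dC"]), unname(d1["dC"]))
})

test_that("dV/dt matches a term-by-term arithmetic oracle on a toy parameter set", {
  # all conductances 1, all reversals 0, V = 10, n = 0.3, C = 2
  p <- chay_params(g_I = 1, g_KV = 1, g_KC = 1, g_L = 1,
                   V_I = 0, V_K = 0, V_L = 0, V_C = 0)
  V <- 10; n <- 0.3; C <- 2
  g <- chay_gating(V, p$lambda_n)
  term_mixed <- g$m_inf^3 * g$h_inf * (0 - V)
  term_kv <- n^4 * (0 - V)
  term_kc <- (C / (1 + C)) * (0 - V)
  term_leak <- (0 - V)
  d <- chay_derivatives(chay_state(V, n, C), p)
  expect_equal(unname(d["dV"]), term_mixed + term_kv + term_kc + term_leak,
               tolerance = 1e-12)
  expect_equal(unname(d["dC"]), p$rho * (g$m_inf^3 * g$h_inf * (0 - V) - p$K_C * C),
               tolerance = 1e-12)
})

test_that("non-finite state components are rejected by name", {
  p <- chay_params()
  s <- chay_state(-40, 0.4, 0.5)
  s[["V"]] <- NaN
  expect_error(chay_derivatives(s, p), "V")
})

test_that("parameter and state invariants are enforced", {
  expect_error(chay_params(g_KV = -1), "conductance")
  expect_error(chay_params(rho = 0), "rho")
  expect_error(chay_params(w_K = 0), "w_K")
  expect_error(chay_state(n = 1.5), "n must")
  expect_error(chay_state(C = -1), "C must")
})

test_that("T = 0 yields a trace holding only the initial state", {
  init <- chay_state(-42, 0.35, 0.6)
  tr <- simulate_chay(chay_params(), init, dt = 0.01, T = 0)
  expect_length(tr$t, 1L)
  expect_equal(tr$V, -42)
  expect_equal(tr$n, 0.35)
  expect_equal(tr$C, 0.6)
})

test_that("deterministic integration is bitwise reproducible and has the expected sample count", {
  p <- chay_params()
  tr1 <- simulate_chay(p, chay_state(), dt = 0.01, T = 2)
  tr2 <- simulate_chay(p, chay_state(), dt = 0.01, T = 2)
  expect_identical(tr1$V, tr2$V)
  expect_length(tr1$t, 201L)
  expect_equal(diff(tr1$t), rep(0.01, 200), tolerance = 1e-12)
})

test_that("rk4 at coarse dt agrees with euler at a 100x finer step", {
  p <- chay_params()
  init <- chay_state(-40, 0.4, 0.5)
  v_rk <- tail(simulate_chay(p, init, dt = 0.005, T = 0.5, method = "rk4")$V, 1)
  v_eu <- tail(simulate_chay(p, init, dt = 0.00005, T = 0.5, method = "euler")$V, 1)
  expect_lt(abs(v_rk - v_eu), 0.05)
})

test_that("halving the step changes V(T) by less than the step-refinement tolerance", {
  p <- chay_params()
  init <- chay_state(-40, 0.4, 0.5)
  v1 <- tail(simulate_chay(p, init, dt = 0.002, T = 0.5, method = "rk4")$V, 1)
  v2 <- tail(simulate_chay(p, init, dt = 0.001, T = 0.5, method = "rk4")$V, 1)
  expect_lt(abs(v1 - v2), 1e-3)
})

test_that("the configured periodic regime produces near-constant ISIs (CV < 0.01)", {
  rg <- chay_regimes()$PD
  tr <- simulate_chay(rg$params, rg$init, dt = rg$dt, T = 60, method = rg$method)
  isi <- extract_isi(detect_spikes(tr, rg$threshold, rg$refractory))$values
  isi <- isi[-(1:20)] # the approach to the limit cycle takes ~20 cycles
  expect_gt(length(isi), 20)
  expect_lt(stats::sd(isi) / mean(isi), 0.01)
})

test_that("integration blow-up raises an error carrying the failure time", {
  p <- chay_params(g_I = 1e7)
  expect_error(simulate_chay(p, chay_state(), dt = 0.1, T = 10, method = "euler"),
               "blow-up at t")
})
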