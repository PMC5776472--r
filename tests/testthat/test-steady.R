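test_that("no sulfide means no anoxygenic photosynthesis", {
  ss <- steady_state_rates(137, 0, model_params())
  expect_equal(ss$gap_e, 0)
  expect_gt(ss$gop_e, 0)
})

test_that("oxygenic and anoxygenic photosynthesis never run simultaneously", {
  p <- model_params()
  gop_max <- steady_state_rates(137, 0, p)$gop_e
  for (h2s in c(0, 0.5, 1, 5, 20)) {
    ss <- steady_state_rates(137, h2s, p)
    if (ss$gop_e > 0.01 * gop_max) {
      expect_lt(h2s, 1)
      expect_equal(ss$gap_e, 0, tolerance = 1e-8)
    }
    if (h2s >= 1) expect_lt(ss$gop_e, 0.01 * gop_max)
  }
})

test_that("blocked-PSII Michaelis limit matches the closed form", {
  # PQ clamped essentially fully oxidized (instant reoxidation) and PSI
  # made non-limiting: anoxygenic rate must collapse to the bare SQR
  # Michaelis curve
  p <- update_params(model_params(), variant = "A", alpha_amp = 0,
                     v_uso = 0, k_pq = 1e8, f1 = 10, v_co2 = 1e4,
                     K_nadph = 1e-4)
  for (h2s in c(5, 44, 150)) {
    gap <- .steady_gap(300, h2s, p)
    expect_equal(gap, p$v_sqr * h2s / (p$Km_sqr + h2s), tolerance = 1e-6)
  }
})

test_that("steady anoxygenic rates agree with a brute-force Euler solution", {
  # integrator-independence oracle: fixed-step explicit Euler at dt = 1e-3
  # on the blocked-PSII subsystem, compared over an H2S grid
  p <- model_params()
  euler_gap <- function(E, h2s, t_end = 200, dt = 1e-3) {
    y <- c(0.5, 0.5, 0.5)   # pq_red, et_red, nadph
    gamma <- 1 + p$gamma_amp * h2s / (p$K_E + h2s)
    delta <- p$K_I / (p$K_I + h2s)
    ms <- h2s / (p$Km_sqr + h2s)
    mu <- h2s / (p$Km_uso + h2s)
    for (i in seq_len(t_end / dt)) {
      k_AP <- p$v_sqr * ms * (1 - y[1])
      k_AP2 <- p$v_uso * mu * (1 - y[2])
      k_PQ <- p$k_pq * y[1] * (1 - y[2])
      k_PSI <- p$f1 * (1 + p$beta * y[1]) * E * y[2] * (1 - y[3])
      k_CO2 <- p$v_co2 * gamma * delta * y[3] / (p$K_nadph + y[3])
      y <- y + dt * c((k_AP - k_PQ) / p$pq_tot,
                      (k_PQ + k_AP2 - k_PSI) / p$et_tot,
                      (k_PSI - k_CO2) / p$nadp_tot)
    }
    p$v_sqr * ms * (1 - y[1]) + p$v_uso * mu * (1 - y[2])
  }
  hs <- c(5, 20, 44, 100)
  ref <- vapply(hs, function(s) euler_gap(23, s), numeric(1))
  got <- vapply(hs, function(s) .steady_gap(23, s, p), numeric(1))
  expect_equal(got, ref, tolerance = 5e-3)
  # monotone rise up to the curve maximum
  fine <- seq(1, 150, by = 5)
  g <- vapply(fine, function(s) .steady_gap(23, s, p), numeric(1))
  up <- seq_len(which.max(g))
  expect_true(all(diff(g[up]) > -1e-9))
})

test_that("full-system and subsystem steady anoxygenic rates agree under DCMU", {
  p <- model_params()
  for (cs in list(c(36, 20), c(137, 44))) {
    full <- steady_state_rates(cs[1], cs[2], p, dcmu = TRUE)
    expect_equal(full$gap_e, .steady_gap(cs[1], cs[2], p), tolerance = 1e-3)
  }
})

test_that("non-convergence is flagged, not silent", {
  ss <- suppressWarnings(
    steady_state_rates(137, 5, model_params(), max_time = 50))
  expect_false(ss$converged)
  expect_warning(steady_state_rates(137, 5, model_params(), max_time = 50),
                 "not converged")
})
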