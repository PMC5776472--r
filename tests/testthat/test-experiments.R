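test_that("PI curve basics: zero at darkness, photoinhibition shapes the tail", {
  p <- model_params()
  pts <- simulate_pi_curve(p, c(0, 23, 137))
  expect_equal(pts$rate_e[pts$irradiance == 0], 0)
  expect_gt(pts$rate_e[pts$irradiance == 137],
            pts$rate_e[pts$irradiance == 23])
  expect_error(simulate_pi_curve(p, c(-5, 100)), "0, 400")
  # without degradation the curve is non-decreasing over the whole range
  p0 <- update_params(p, k_d_max = 0)
  E <- c(23, 60, 100, 137, 180, 250, 289)
  g <- simulate_pi_curve(p0, E)$rate_e
  expect_true(all(diff(g) > -1e-8))
})

test_that("instant OEC deinhibition collapses the recovery lag", {
  p_fast <- update_params(model_params(), k_s2 = 1e3)
  gop_max <- steady_state_rates(137, 0, p_fast)$gop_e
  tr <- simulate_recovery(137, p_fast, recovery_duration = 1200,
                          sampling_dt = 5)
  lag <- recovery_lag(tr, gop_max)
  expect_lt(lag, 120)   # seconds, essentially immediate
})

test_that("post-lag recovery is slower at higher irradiance", {
  p <- model_params()
  t90 <- sapply(c(23, 137), function(E) {
    tr <- simulate_recovery(E, p, recovery_duration = 5 * 3600,
                            sampling_dt = 60)
    plateau <- max(tr$gop_e)
    gop_max <- steady_state_rates(137, 0, p)$gop_e
    lag <- recovery_lag(tr, gop_max)
    tr$times[which(tr$gop_e > 0.9 * plateau)[1]] - lag
  })
  expect_gt(t90[2], t90[1])
})

test_that("preconditioning below full inhibition is rejected", {
  expect_error(simulate_recovery(137, model_params(),
                                 preconditioning = list(h2s = 0.5,
                                                        duration = 600)),
               ">= 1")
})

test_that("diel cycle without sulfide supply is purely oxygenic", {
  cfg <- diel_config(h2s_supply_uM_s = 0, duration_h = 24,
                     sampling_dt = 300)
  res <- simulate_diel(cfg, model_params(), h2s_init = 0)
  expect_true(all(res$trajectory$gap_e < 1e-9))
  expect_true(any(res$trajectory$gop_e > 0))
  expect_true(all(is.na(res$summary$ap_window)) ||
                all(res$summary$ap_window == 0))
  # oxygenic activity tracks the light window
  dark <- res$trajectory$irradiance == 0
  expect_lt(max(res$trajectory$gop_e[dark]),
            0.2 * max(res$trajectory$gop_e))
})

test_that("diel summary reports the morning switching lag", {
  res <- simulate_diel(diel_config(sampling_dt = 300), model_params())
  s <- res$summary
  expect_true(is.finite(s$lag_minutes))
  expect_gt(s$lag_minutes, 0)
  expect_false(any(is.na(s$ap_window)))
  expect_false(any(is.na(s$op_window)))
  # anoxygenic phase starts before the oxygenic one
  expect_lt(s$ap_window[1], s$op_window[1])
})

test_that("more sulfide supply shortens or abolishes the oxygenic window", {
  p <- model_params()
  base_supply <- diel_config()$h2s_supply_uM_s
  op_len <- sapply(c(0.5, 1, 2) * base_supply, function(f) {
    res <- simulate_diel(diel_config(h2s_supply_uM_s = f,
                                     sampling_dt = 600), p)
    w <- res$summary$op_window
    if (any(is.na(w))) 0 else diff(w)
  })
  expect_true(all(diff(op_len) <= 1e-9))
})
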