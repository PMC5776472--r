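test_that("all-dark protocol stays flat with no activity", {
  pr <- experiment_protocol(duration = 300, sampling_dt = 1,
                            h2s_outgassing_k = 0)
  tr <- simulate_experiment(pr, model_params(),
                            initial = model_state(nadph = 0))
  expect_true(all(tr$gop_e == 0))
  expect_true(all(tr$gap_e == 0))
  expect_true(all(tr$trace$h2s_uM == 0))
  expect_true(all(tr$trace$o2_uM == 0))
})

test_that("injection decay matches the closed-form mixing/outgassing solution", {
  # with consumption disabled the local H2S obeys
  # dh/dt = A/tau exp(-(t-t0)/tau) - k h, whose solution is
  # A/(1 - k tau) (exp(-k (t-t0)) - exp(-(t-t0)/tau))
  p <- update_params(model_params(), v_sqr = 0, v_uso = 0)
  A <- 80; tau <- 30; k <- 2e-3; t0 <- 100
  pr <- experiment_protocol(
    duration = 1500,
    light_schedule = data.frame(t_start = 0, irradiance = 137),
    injections = data.frame(t = t0, amount_uM = A, tau_s = tau),
    h2s_outgassing_k = k, sampling_dt = 5)
  tr <- simulate_experiment(pr, p)
  tt <- tr$times[tr$times > t0]
  expected <- A / (1 - k * tau) *
    (exp(-k * (tt - t0)) - exp(-(tt - t0) / tau))
  got <- tr$states[tr$times > t0, "h2s"]
  expect_equal(got, expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("DCMU abolishes O2 production but sulfide still drives GAP", {
  p <- model_params()
  pr <- experiment_protocol(
    duration = 900,
    light_schedule = data.frame(t_start = 0, irradiance = 137),
    injections = data.frame(t = 60, amount_uM = 60, tau_s = 60),
    dcmu_at = 0, sampling_dt = 1)
  tr <- simulate_experiment(pr, p)
  expect_true(all(tr$gop_e == 0))
  expect_true(all(tr$trace$o2_uM == 0))
  i_peak <- which.max(tr$states[, "h2s"])
  expect_gt(tr$gap_e[i_peak], 10 * tr$gap_e[2])
})

test_that("state is continuous across light switches", {
  p <- model_params()
  pr <- experiment_protocol(
    duration = 400,
    light_schedule = data.frame(t_start = c(0, 200),
                                irradiance = c(137, 0)),
    sampling_dt = 0.5)
  tr <- simulate_experiment(pr, p, initial = mid_state(h2s = 10))
  i <- which(tr$times == 200)
  jump <- abs(tr$states[i, ] - tr$states[i - 1L, ])
  expect_true(all(jump[1:12] < 0.05))   # pools move smoothly
  # but the rate response is discontinuous: excitation stops instantly
  expect_gt(tr$rates[i - 1L, "k_L"], 0)
  expect_identical(unname(tr$rates[i, "k_L"]), 0)
})

test_that("identical protocols reproduce bitwise-identical traces", {
  p <- model_params()
  pr <- experiment_protocol(
    duration = 120,
    light_schedule = data.frame(t_start = 0, irradiance = 100),
    injections = data.frame(t = 30, amount_uM = 20, tau_s = 15),
    sampling_dt = 0.5)
  a <- simulate_experiment(pr, p, initial = mid_state(h2s = 5))
  b <- simulate_experiment(pr, p, initial = mid_state(h2s = 5))
  expect_identical(a$trace, b$trace)
  expect_identical(a$states, b$states)
})

test_that("pool conservation holds along long trajectories with events", {
  p <- model_params()
  pr <- experiment_protocol(
    duration = 1e4,
    light_schedule = data.frame(t_start = c(0, 3000, 6000),
                                irradiance = c(137, 0, 23)),
    injections = data.frame(t = 1000, amount_uM = 50, tau_s = 60),
    dcmu_at = 8000, sampling_dt = 20)
  tr <- simulate_experiment(pr, p, initial = model_state(h2s = 2,
                                                         nadph = 0.5))
  st <- tr$states
  sums <- cbind(rowSums(st[, c("psii_g", "psii_e", "psii_d")]),
                rowSums(st[, c("oec_a", "oec_ox", "oec_i")]),
                rowSums(st[, c("pq_ox", "pq_red")]),
                rowSums(st[, c("et_ox", "et_red")]),
                rowSums(st[, c("nadp", "nadph")]))
  expect_true(all(abs(sums - 1) < 1e-8))
  # cumulative quantities never decrease
  expect_true(all(diff(st[, "s0_cum"]) > -1e-8))
  expect_true(all(diff(st[, "c_fix_cum"]) > -1e-8))
})
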