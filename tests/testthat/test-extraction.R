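test_that("speciation identities and the full-equilibrium oracle hold", {
  expect_equal(speciate(10, 6.98, pk1 = 6.98), 20)   # half-dissociation
  expect_equal(speciate(0, 7.5), 0)
  # strictly increasing in pH at fixed H2S
  ph <- seq(5, 9, by = 0.25)
  expect_true(all(diff(speciate(10, ph)) > 0))
  # oracle: full two-pKa equilibrium (pK2 = 12.9); below pH 8 the S2-
  # term is negligible and the one-pKa form must agree within 0.5%
  full <- function(h2s, ph, pk1 = 6.98, pk2 = 12.9)
    h2s * (1 + 10^(ph - pk1) + 10^(2 * ph - pk1 - pk2))
  expect_equal(speciate(10, 7.2, 6.98), full(10, 7.2), tolerance = 5e-3)
})

test_that("GOP extraction recovers an exact linear O2 decline", {
  t <- seq(0, 30, by = 0.25)
  o2 <- ifelse(t < 10, 50, 50 - 0.25 * (t - 10))
  tr <- microsensor_trace(t, o2, rep(0, length(t)), rep(7.2, length(t)),
                          meta = list(light_schedule =
                                        data.frame(t_start = 0,
                                                   irradiance = 137)))
  pt <- extract_gop(tr, t_dark = 10, window = 2)
  expect_equal(pt$rate_raw, 0.25, tolerance = 1e-10)
  expect_equal(pt$rate_e, 1.0, tolerance = 1e-10)
  expect_equal(pt$irradiance, 137)
  # flat O2 -> zero rate with a warning flag
  tr2 <- microsensor_trace(t, rep(50, length(t)), rep(0, length(t)),
                           rep(7.2, length(t)))
  pt2 <- extract_gop(tr2, 10, 2)
  expect_equal(pt2$rate_e, 0)
  expect_equal(pt2$flag, "nonpositive_slope")
})

test_that("GAP extraction handles sign, scale and drift bookkeeping", {
  # at pH = pK1 the speciation factor is exactly 2, so an H2S rise of
  # 0.15 uM/s is an S_tot rise of 0.30 uM/s
  t <- seq(0, 60, by = 0.25)
  h2s <- ifelse(t < 30, 40, 40 + 0.15 * (t - 30))
  tr <- microsensor_trace(t, rep(0, length(t)), h2s,
                          rep(6.98, length(t)), meta = list(pk1 = 6.98))
  pt <- extract_gap(tr, t_dark = 30, window = 2)
  expect_equal(pt$rate_raw, 0.30, tolerance = 1e-9)
  expect_equal(pt$rate_e, 0.60, tolerance = 1e-9)
  expect_equal(pt$flag, "ok")
  # constant channels -> zero rate
  tr0 <- microsensor_trace(t, rep(0, length(t)), rep(40, length(t)),
                           rep(7.1, length(t)))
  expect_equal(extract_gap(tr0, 30, 2)$rate_e, 0)
  # an abiotic linear drift present on both sides is subtracted out
  h2s_d <- h2s - 0.02 * t
  trd <- microsensor_trace(t, rep(0, length(t)), h2s_d,
                           rep(6.98, length(t)), meta = list(pk1 = 6.98))
  ptd <- extract_gap(trd, 30, 2)
  expect_equal(ptd$rate_raw, 0.30, tolerance = 1e-6)
  # without pre-dark coverage the point is flagged as uncorrected
  sel <- t >= 29.5
  trs <- microsensor_trace(t[sel] , rep(0, sum(sel)), h2s[sel],
                           rep(6.98, sum(sel)), meta = list(pk1 = 6.98))
  expect_equal(extract_gap(trs, 30, 2)$flag, "no_drift_reference")
})

test_that("GAP extraction requires a pH channel", {
  t <- seq(0, 60, by = 0.25)
  tr <- microsensor_trace(t, rep(0, length(t)), rep(40, length(t)),
                          ph = NULL)
  expect_error(extract_gap(tr, 30, 2), "pH")
})

test_that("windows crossing protocol events are rejected", {
  t <- seq(0, 60, by = 0.25)
  tr <- microsensor_trace(t, 50 - 0.1 * t, rep(0, length(t)),
                          rep(7.2, length(t)),
                          meta = list(event_times = c(0, 30, 31)))
  expect_error(extract_gop(tr, 30, 2), "event")
  # too few samples also fails
  tr2 <- microsensor_trace(seq(0, 60, by = 2), rep(50, 31), rep(0, 31),
                           rep(7.2, 31))
  expect_error(extract_gop(tr2, 30, 2), "samples")
})

test_that("normalization is exact and idempotent", {
  pts <- rbind(rate_point(137, 0, 0.25, 1.0, "GOP"),
               rate_point(137, 44, 1.0, 2.0, "GAP"))
  n1 <- normalize_rates(pts, gop_max = 1.0)
  expect_equal(n1$rate_norm, c(1.0, 2.0))
  expect_identical(normalize_rates(n1, 1.0), n1)
  expect_error(normalize_rates(pts, 0), "positive")
})

test_that("extraction recovers simulated steady rates (round trip)", {
  p <- model_params()
  # GOP at 137: steady light phase then darkening
  ss <- steady_state_rates(137, 0, p)
  init <- ss$state
  init["o2"] <- ss$gop_e / 4 / 2e-3   # O2 at production/efflux balance
  class(init) <- "model_state"
  pr <- experiment_protocol(
    duration = 220,
    light_schedule = data.frame(t_start = c(0, 200),
                                irradiance = c(137, 0)),
    o2_exchange_k = 2e-3, sampling_dt = 0.25)
  tr <- simulate_experiment(pr, p, initial = init)
  pt <- extract_gop(tr$trace, 200, window = 2)
  expect_equal(pt$rate_e, ss$gop_e, tolerance = 0.05)
})
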