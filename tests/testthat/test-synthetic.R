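test_that("zero noise reproduces the simulator output exactly", {
  sp <- scenario_spec("injection_light", irradiance = 137,
                      noise = noise_model(0, 0, 0, seed = 5),
                      sampling_dt = 1)
  out <- generate_trace(sp)
  expect_equal(out$trace$o2_uM, out$trajectory$trace$o2_uM)
  expect_equal(out$trace$h2s_uM, out$trajectory$trace$h2s_uM)
  expect_equal(out$trace$pH, out$trajectory$trace$pH)
})

test_that("trace generation is reproducible for a fixed seed", {
  sp <- scenario_spec("injection_light", irradiance = 137,
                      noise = noise_model(seed = 9), sampling_dt = 1)
  a <- generate_trace(sp)
  b <- generate_trace(sp)
  expect_identical(a$trace, b$trace)
  sp2 <- scenario_spec("injection_light", irradiance = 137,
                       noise = noise_model(seed = 10), sampling_dt = 1)
  c <- generate_trace(sp2)
  expect_false(identical(a$trace$o2_uM, c$trace$o2_uM))
})

test_that("ground truth always accompanies the noisy trace", {
  sp <- scenario_spec("injection_dark", irradiance = 0, sampling_dt = 1)
  out <- generate_trace(sp)
  expect_true(all(c("time_s", "gop_e", "gap_e", "h2s") %in%
                    names(out$ground_truth)))
  expect_equal(nrow(out$ground_truth), nrow(out$trace))
  # dark injection: sulfide present, no O2 at all; sulfide oxidation only
  # transiently fills the small dark-blocked carrier pools, then stops
  gt <- out$ground_truth
  expect_gt(max(gt$h2s), 10)
  expect_true(all(gt$gop_e == 0))
  expect_equal(gt$gap_e[nrow(gt)], 0, tolerance = 1e-6)
  expect_lt(max(out$trajectory$states[, "s0_cum"]), 1)
})

test_that("slow sulfide injection in the light reproduces the GAP optimum", {
  sp <- scenario_spec("injection_light", irradiance = 137,
                      injection_uM = 400, injection_tau_s = 300,
                      noise = noise_model(0, 0, 0), sampling_dt = 2)
  out <- generate_trace(sp)
  gt <- out$ground_truth
  # ground-truth GAP peaks near the optimal local H2S of ~44 uM
  rising <- gt$h2s > 1 & gt$time_s > 300 &
    gt$time_s <= gt$time_s[which.max(gt$h2s)]
  h_at_peak <- gt$h2s[rising][which.max(gt$gap_e[rising])]
  expect_gt(h_at_peak, 34)
  expect_lt(h_at_peak, 54)
})

test_that("generated fit datasets are structurally valid and close to truth", {
  p <- model_params()
  ds <- generate_fit_dataset(p, noise = noise_model(0, 0, 0, seed = 1),
                             seed = 1, irradiances = c(36, 137),
                             h2s_levels = c(5, 20, 44, 80),
                             recovery_irradiances = NULL,
                             rate_rel_sd = 0)
  expect_s3_class(ds, "fit_dataset")
  gmax <- steady_state_rates(137, 0, p)$gop_e
  expect_equal(ds$gop_max, gmax, tolerance = 0.05)
  for (nm in names(ds$gap_curves)) {
    cv <- ds$gap_curves[[nm]]
    truth <- vapply(cv$h2s, function(s)
      .steady_gap(as.numeric(nm), s, p), numeric(1)) / gmax
    expect_equal(cv$rate_norm, truth, tolerance = 0.10)
  }
})

test_that("dataset regeneration with another seed moves points only within noise", {
  p <- model_params()
  mk <- function(seed) generate_fit_dataset(
    p, noise = noise_model(seed = seed), seed = seed,
    irradiances = 137, h2s_levels = c(10, 30, 44, 80),
    recovery_irradiances = NULL, rate_rel_sd = 0.05)
  a <- mk(1); b <- mk(2)
  ra <- a$gap_curves[["137"]]$rate_norm
  rb <- b$gap_curves[["137"]]$rate_norm
  expect_false(identical(ra, rb))
  # medians agree within a few noise widths (replicate noise enters both
  # the points and the GOP_max they are normalized to)
  expect_equal(stats::median(ra), stats::median(rb), tolerance = 0.25)
})
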