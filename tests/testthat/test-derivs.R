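test_that("conserved pool sums have exactly zero derivative", {
  p <- model_params()
  for (s in random_states(20)) {
    d <- state_derivative(s, 137, p)
    # the ground/active states close their pools exactly, so adding them
    # last cancels the partial sum bit-for-bit
    expect_identical(d[["psii_e"]] + d[["psii_d"]] + d[["psii_g"]], 0)
    expect_identical(d[["oec_ox"]] + d[["oec_i"]] + d[["oec_a"]], 0)
    expect_identical(d[["pq_ox"]] + d[["pq_red"]], 0)
    expect_identical(d[["et_ox"]] + d[["et_red"]], 0)
    expect_identical(d[["nadp"]] + d[["nadph"]], 0)
  }
})

test_that("quiescent dark state is stationary except for PSII repair", {
  p <- model_params()
  s <- model_state(nadph = 0)  # everything at rest, nothing reduced
  d <- state_derivative(s, 0, p)
  expect_true(all(abs(d) < 1e-15))
  s2 <- model_state(psii_g = 0.7, psii_d = 0.3, nadph = 0)
  d2 <- state_derivative(s2, 0, p)
  expect_equal(unname(d2[["psii_d"]]), -p$k_r * 0.3)
  expect_equal(unname(d2[["psii_g"]]), p$k_r * 0.3)
  others <- setdiff(names(d2), c("psii_g", "psii_d"))
  expect_true(all(abs(d2[others]) < 1e-15))
})

test_that("steady illuminated chain without sulfide passes the electron-balance oracle", {
  p <- model_params()
  ss <- steady_state_rates(100, 0, p)
  expect_true(ss$converged)
  r <- rate_vector(ss$state, 100, p)
  # flux equality through the chain at steady state
  flux <- r[["k_OP"]]
  expect_equal(unname(4 * r[["k_O2"]]), unname(flux), tolerance = 1e-5)
  expect_equal(unname(r[["k_PSI"]]), unname(flux), tolerance = 1e-5)
  expect_equal(unname(r[["k_CO2"]]), unname(flux), tolerance = 1e-5)
})

test_that("electron balance closes over a dynamic trajectory", {
  # independently coded flux-balance check: electrons in from sulfide and
  # water equal electrons fixed plus the change in pool electron content
  p <- model_params()
  pr <- experiment_protocol(
    duration = 600,
    light_schedule = data.frame(t_start = c(0, 200), irradiance = c(137, 36)),
    h2s_outgassing_k = 0, o2_exchange_k = 0,
    sampling_dt = 1, ph_coef = 0)
  init <- model_state(h2s = 30, nadph = 0.5)
  tr <- simulate_experiment(pr, p, initial = init)
  st <- tr$states
  for (i in c(100, 300, 599)) {
    s0 <- st[1, ]; s1 <- st[i + 1, ]
    # S_tot consumed is accumulated in the zero-valent sulfur counter
    e_in <- 2 * (s1[["s0_cum"]] - s0[["s0_cum"]]) +
      4 * (s1[["o2"]] - s0[["o2"]])
    content <- function(s) {
      s <- stats::setNames(as.numeric(s), names(s))
      class(s) <- "model_state"
      electron_content(s, p)
    }
    e_out <- 4 * (s1[["c_fix_cum"]] - s0[["c_fix_cum"]]) +
      (content(s1) - content(s0))
    expect_equal(e_in, e_out, tolerance = 1e-3)
  }
})

test_that("external exchange terms must be finite", {
  expect_error(
    state_derivative(mid_state(), 100, model_params(),
                     external = list(h2s_source_rate = Inf)),
    "finite")
})
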