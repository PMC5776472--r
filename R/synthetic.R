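#' Sensor noise model
#'
#' Gaussian, independent per-sample noise plus optional slow linear drift
#' for each channel of a synthetic microsensor trace.  Defaults are
#' anchored to sensor-grade detection limits: 0.3 uM for O2, 0.2 uM for
#' H2S, 0.005 pH units.
#'
#' @param o2_sd,h2s_sd,ph_sd per-sample standard deviations (uM, uM, pH).
#' @param o2_drift,h2s_drift,ph_drift linear drift rates (uM/s, uM/s,
#'   pH/s).
#' @param seed integer seed making generation reproducible.
#' @return a `noise_model` object.
#' @export
noise_model <- function(o2_sd = 0.3, h2s_sd = 0.2, ph_sd = 0.005,
                        o2_drift = 0, h2s_drift = 0, ph_drift = 0,
                        seed = 1) {
  if (any(c(o2_sd, h2s_sd, ph_sd) < 0)) stop("noise sds must be >= 0")
  nm <- list(o2_sd = o2_sd, h2s_sd = h2s_sd, ph_sd = ph_sd,
             o2_drift = o2_drift, h2s_drift = h2s_drift,
             ph_drift = ph_drift, seed = seed)
  class(nm) <- "noise_model"
  nm
}

#' Scenario specification for synthetic traces
#'
#' @param scenario one of `"pi_curve"`, `"injection_light"`,
#'   `"injection_dark"`, `"dcmu_injection"`, `"recovery"`, `"diel"`.
#' @param irradiance irradiance (umol photons m-2 s-1); for `"pi_curve"` a
#'   vector of levels.
#' @param injection_uM injected H2S amount (uM) for the injection
#'   scenarios.
#' @param injection_tau_s mixing time constant of the injection (s).
#' @param true_params generating `model_params`.
#' @param noise a [noise_model()].
#' @param sampling_dt sampling interval (s); default 0.25 (sub-second
#'   sensor response).
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(scenario = c("injection_light", "injection_dark",
                                       "dcmu_injection", "pi_curve",
                                       "recovery", "diel"),
                          irradiance = 137, injection_uM = 300,
                          injection_tau_s = 300,
                          true_params = model_params(),
                          noise = noise_model(),
                          sampling_dt = 0.25) {
  scenario <- match.arg(scenario)
  if (scenario == "pi_curve" && length(irradiance) < 4L)
    stop("pi_curve scenario needs >= 4 irradiance levels")
  if (scenario %in% c("injection_light", "injection_dark",
                      "dcmu_injection") && injection_uM <= 0)
    stop("injection scenarios need injection_uM > 0")
  sp <- list(scenario = scenario, irradiance = irradiance,
             injection_uM = injection_uM,
             injection_tau_s = injection_tau_s,
             true_params = true_params, noise = noise,
             sampling_dt = sampling_dt)
  class(sp) <- "scenario_spec"
  sp
}

.apply_noise <- function(trace, nm) {
  set.seed(nm$seed)
  t <- trace$time_s
  n <- length(t)
  o2 <- trace$o2_uM + stats::rnorm(n, 0, nm$o2_sd) + nm$o2_drift * t
  h2s <- trace$h2s_uM + stats::rnorm(n, 0, nm$h2s_sd) + nm$h2s_drift * t
  ph <- trace$pH + stats::rnorm(n, 0, nm$ph_sd) + nm$ph_drift * t
  # clip sensor noise explicitly at zero (flagged via attribute)
  clipped <- sum(o2 < 0) + sum(h2s < 0)
  out <- microsensor_trace(t, pmax(o2, 0), pmax(h2s, 0), ph,
                           meta = attr(trace, "meta"))
  attr(out, "n_clipped") <- clipped
  out
}

#' Generate a synthetic microsensor trace with ground truth
#'
#' Simulates the scenario with [simulate_experiment()] (or the dedicated
#' recovery / diel drivers), then overlays per-sample sensor noise and
#' drift.  The noise-free ground truth (instantaneous GOP_e and GAP_e) is
#' always returned alongside so downstream tests never rely on digitized
#' figures.
#'
#' @param spec a [scenario_spec()].
#' @return list with `trace` (noisy [microsensor_trace()]), `ground_truth`
#'   (data.frame `time_s, gop_e, gap_e, h2s, irradiance`) and `trajectory`
#'   (the underlying noise-free simulation).
#' @export
generate_trace <- function(spec) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  p <- spec$true_params
  traj <- switch(
    spec$scenario,
    injection_light = ,
    dcmu_injection = {
      pr <- experiment_protocol(
        duration = 3600,
        light_schedule = data.frame(t_start = 0,
                                    irradiance = spec$irradiance[1]),
        injections = data.frame(t = 300, amount_uM = spec$injection_uM,
                                tau_s = spec$injection_tau_s),
        dcmu_at = if (spec$scenario == "dcmu_injection") 0 else NULL,
        sampling_dt = spec$sampling_dt)
      simulate_experiment(pr, p)
    },
    injection_dark = {
      pr <- experiment_protocol(
        duration = 3600,
        light_schedule = data.frame(t_start = 0, irradiance = 0),
        injections = data.frame(t = 300, amount_uM = spec$injection_uM,
                                tau_s = spec$injection_tau_s),
        sampling_dt = spec$sampling_dt)
      simulate_experiment(pr, p)
    },
    pi_curve = {
      # hold each irradiance, then a short dark shift for GOP extraction
      hold <- 600; dark <- 30
      k <- length(spec$irradiance)
      starts <- (seq_len(k) - 1L) * (hold + dark)
      ls <- data.frame(
        t_start = sort(c(starts, starts + hold)),
        irradiance = as.vector(rbind(spec$irradiance, 0)))
      pr <- experiment_protocol(duration = k * (hold + dark),
                                light_schedule = ls,
                                sampling_dt = spec$sampling_dt)
      simulate_experiment(pr, p)
    },
    recovery = simulate_recovery(spec$irradiance[1], p,
                                 sampling_dt = spec$sampling_dt),
    diel = simulate_diel(diel_config(), p)$trajectory)

  truth <- data.frame(time_s = traj$times, gop_e = traj$gop_e,
                      gap_e = traj$gap_e, h2s = traj$states[, "h2s"],
                      irradiance = traj$irradiance)
  list(trace = .apply_noise(traj$trace, spec$noise),
       ground_truth = truth, trajectory = traj)
}

#' Generate a calibration dataset from known parameters
#'
#' Builds the data structure the calibration stage fits: GAP-versus-H2S
#' curves at the four experimental irradiances and GOP recovery series at
#' two of them, generated by simulating each measurement and passing the
#' resulting traces through the rate-extraction stage (never read off the
#' ground truth), so extraction error is part of the fitting surface.
#'
#' Each GAP point is measured as in the aquarium: under DCMU, a constant
#' sulfide supply holds the local H2S near the target level, the chain is
#' given time to reach steady state, and a light-dark shift is performed;
#' [extract_gap()] recovers the rate from the noisy trace.  GOP_max is
#' itself measured by a light-dark shift at 137 umol photons m-2 s-1
#' without sulfide.  On top of sensor noise, each extracted rate receives a
#' multiplicative replicate error with standard deviation `rate_rel_sd`
#' (default 5%), representing biological variability between biofilm
#' spots.
#'
#' @param true_params generating `model_params`.
#' @param noise a [noise_model()]; its `seed` is combined with `seed`.
#' @param seed integer; master seed for this dataset.
#' @param irradiances GAP curve irradiances.
#' @param h2s_levels H2S levels per curve (uM).
#' @param n_replicates independent replicate measurements per level (two
#'   biofilm samples per intensity, as in the experimental design).
#' @param recovery_irradiances irradiances for GOP recovery series (set
#'   `NULL` to skip, e.g. for fast GAP-only datasets).
#' @param rate_rel_sd replicate-level relative rate error.
#' @param window light-dark slope window for the generated measurements
#'   (s); longer than the 2 s default so sensor noise averages down.
#' @return a [fit_dataset()] with attribute `true_params`.
#' @export
generate_fit_dataset <- function(true_params = model_params(),
                                 noise = noise_model(),
                                 seed = 1,
                                 irradiances = c(23, 36, 137, 180),
                                 h2s_levels = c(2, 5, 10, 15, 22, 32, 44,
                                                60, 100, 150),
                                 n_replicates = 2,
                                 recovery_irradiances = c(23, 137),
                                 rate_rel_sd = 0.05,
                                 window = 30) {
  p <- true_params
  settle <- 400
  t_dark <- settle
  k_out <- 5e-4
  ph_base <- 7.2; pk1 <- 6.98
  spec_f <- 1 + 10^(ph_base - pk1)
  counter <- 0L

  measure_gap <- function(E, h2s_target) {
    counter <<- counter + 1L
    gap_ss <- .steady_gap(E, h2s_target, p)
    src <- k_out * h2s_target + gap_ss / (2 * spec_f)
    pr <- experiment_protocol(
      duration = settle + window + 5,
      light_schedule = data.frame(t_start = c(0, t_dark),
                                  irradiance = c(E, 0)),
      dcmu_at = 0, h2s_outgassing_k = k_out,
      ph_coef = 0, sampling_dt = 0.25)
    init <- model_state(h2s = h2s_target, nadph = 0.5, oec_a = 0,
                        oec_i = 1)
    traj <- simulate_experiment(pr, p, initial = init,
                                extra_source = function(t) src)
    nm <- noise
    nm$seed <- noise$seed + 1000L * seed + counter
    noisy <- .apply_noise(traj$trace, nm)
    extract_gap(noisy, t_dark, window = window, pk1 = pk1,
                ref_window = window)
  }

  measure_gop_max <- function() {
    counter <<- counter + 1L
    pr <- experiment_protocol(
      duration = settle + window + 5,
      light_schedule = data.frame(t_start = c(0, t_dark),
                                  irradiance = c(137, 0)),
      o2_exchange_k = 1e-3, ph_coef = 0, sampling_dt = 0.25)
    ss <- steady_state_rates(137, 0, p)
    init <- ss$state
    init["o2"] <- ss$gop_e / 4 / pr$o2_exchange_k  # production = efflux
    class(init) <- "model_state"
    traj <- simulate_experiment(pr, p, initial = init)
    nm <- noise
    nm$seed <- noise$seed + 1000L * seed + counter
    noisy <- .apply_noise(traj$trace, nm)
    extract_gop(noisy, t_dark, window = window)
  }

  set.seed(seed)
  repl_err <- function() exp(stats::rnorm(1, 0, rate_rel_sd))

  gop_max_pt <- measure_gop_max()
  gop_max <- gop_max_pt$rate_e
  if (gop_max <= 0) stop("generated GOP_max is non-positive")

  gap_curves <- list()
  for (E in irradiances) {
    pts <- lapply(rep(h2s_levels, n_replicates), function(s) {
      pt <- measure_gap(E, s)
      data.frame(h2s = pt$h2s_at_rate,
                 rate_norm = pmin(pt$rate_e * repl_err() / gop_max, 2.5))
    })
    gap_curves[[as.character(E)]] <- do.call(rbind, pts)
  }

  recovery_series <- list()
  for (E in recovery_irradiances) {
    traj <- simulate_recovery(E, p, sampling_dt = 60)
    tt <- seq(600, max(traj$times), by = 600)
    gop <- stats::approx(traj$times, traj$gop_e, xout = tt)$y
    recovery_series[[as.character(E)]] <-
      data.frame(time_s = tt,
                 gop_norm = pmax(gop / gop_max +
                                   stats::rnorm(length(tt), 0,
                                                rate_rel_sd * 0.5), 0))
  }

  ds <- fit_dataset(gap_curves, recovery_series, gop_max = gop_max,
                    provenance = "synthetic")
  attr(ds, "true_params") <- p
  attr(ds, "seed") <- seed
  ds
}
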