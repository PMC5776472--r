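#' Steady-state photosynthesis-irradiance (PI) curve
#'
#' Computes the steady gross oxygenic rate at each irradiance in the absence
#' of sulfide.  With the default calibration the curve rises, saturates near
#' the optimum and declines at supra-optimal light through photoinhibition
#' (PSII degradation outpacing repair).
#'
#' @param params a [model_params()] object.
#' @param irradiances vector of irradiances (umol photons m-2 s-1, within
#'   0-400).
#' @param ... passed to [steady_state_rates()].
#' @return a `rate_point` data.frame (one GOP row per irradiance).
#' @examples
#' \donttest{
#' pi <- simulate_pi_curve(model_params(), c(10, 50, 137, 200))
#' }
#' @export
simulate_pi_curve <- function(params, irradiances, ...) {
  if (any(irradiances < 0 | irradiances > 400))
    stop("irradiances must lie within [0, 400]")
  rows <- lapply(irradiances, function(E) {
    g <- if (E == 0) list(gop_e = 0)
         else steady_state_rates(E, 0, params, ...)
    rate_point(irradiance = E, h2s_at_rate = 0,
               rate_raw = g$gop_e / 4, rate_e = g$gop_e,
               kind = "GOP", dcmu = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate recovery of oxygenic photosynthesis after sulfide depletion
#'
#' Preconditions the model at a fixed H2S concentration (clamped, >= 1 uM
#' so PSII is fully inhibited) under the given irradiance, then sets H2S to
#' zero and follows the return of gross oxygenic photosynthesis.  The lag
#' before measurable recovery is governed by the slow release of H2S from
#' the oxygen-evolving complex; the post-lag recovery rate is slower at
#' higher irradiance because photoinhibition keeps pace with repair.
#'
#' @param irradiance umol photons m-2 s-1.
#' @param params a [model_params()] object.
#' @param preconditioning list with `h2s` (uM, >= 1) and `duration` (s).
#' @param recovery_duration time followed after depletion (s).
#' @param sampling_dt trace sampling step (s).
#' @return a `trajectory` covering the recovery phase only (time 0 = moment
#'   of depletion), with the preconditioned state as initial condition.
#' @export
simulate_recovery <- function(irradiance, params,
                              preconditioning = list(h2s = 50,
                                                     duration = 1800),
                              recovery_duration = 4 * 3600,
                              sampling_dt = 10) {
  if (preconditioning$h2s < 1)
    stop("preconditioning H2S must be >= 1 uM (full GOP inhibition)")
  pre <- experiment_protocol(
    duration = preconditioning$duration,
    light_schedule = data.frame(t_start = 0, irradiance = irradiance),
    h2s_clamp = preconditioning$h2s, sampling_dt = preconditioning$duration)
  pre_traj <- simulate_experiment(pre, params)
  s <- pre_traj$states[nrow(pre_traj$states), ]
  s["h2s"] <- 0
  class(s) <- "model_state"

  post <- experiment_protocol(
    duration = recovery_duration,
    light_schedule = data.frame(t_start = 0, irradiance = irradiance),
    h2s_clamp = 0, sampling_dt = sampling_dt)
  simulate_experiment(post, params, initial = s)
}

#' Lag before measurable GOP recovery
#'
#' First time at which the gross oxygenic rate exceeds `threshold` times
#' `gop_max` in a recovery trajectory.
#'
#' @param traj a trajectory from [simulate_recovery()].
#' @param gop_max reference maximum GOP_e (electron uM/s).
#' @param threshold fraction of `gop_max` counted as measurable (default
#'   0.05).
#' @return lag in seconds (`NA` if never crossed).
#' @export
recovery_lag <- function(traj, gop_max, threshold = 0.05) {
  idx <- which(traj$gop_e > threshold * gop_max)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(traj$times[1])
  # linear interpolation across the crossing sample
  t0 <- traj$times[i - 1L]; t1 <- traj$times[i]
  g0 <- traj$gop_e[i - 1L]; g1 <- traj$gop_e[i]
  t0 + (threshold * gop_max - g0) / (g1 - g0) * (t1 - t0)
}

#' Simulate a diel cycle in the lumped mat surface layer
#'
#' Irradiance follows a half-sinusoid over the photoperiod; H2S is supplied
#' at a constant flux and lost by outgassing and photosynthetic
#' consumption.  In the morning the accumulated sulfide drives anoxygenic
#' photosynthesis; once rising light depletes it, oxygenic photosynthesis
#' starts only after the deinhibition lag; in the evening sulfide
#' re-accumulates and the layer returns to anoxygenic activity.
#'
#' @param cfg a [diel_config()].
#' @param params a [model_params()] object.
#' @param h2s_init initial H2S (uM); default the supply/outgassing balance.
#' @return list with `trajectory` and `summary` (list `ap_window`,
#'   `op_window` as `c(start, end)` in hours, and `lag_minutes`, the delay
#'   between the end of morning anoxygenic activity and the onset of
#'   oxygenic activity).
#' @export
simulate_diel <- function(cfg, params, h2s_init = NULL) {
  if (!inherits(cfg, "diel_config")) stop("cfg must be a diel_config")
  if (is.null(h2s_init))
    h2s_init <- if (cfg$h2s_outgassing_k > 0)
      cfg$h2s_supply_uM_s / cfg$h2s_outgassing_k else 0
  pr <- experiment_protocol(
    duration = cfg$duration_h * 3600,
    light_schedule = data.frame(t_start = 0, irradiance = 0),
    h2s_outgassing_k = cfg$h2s_outgassing_k,
    sampling_dt = cfg$sampling_dt)
  init <- model_state(h2s = h2s_init, nadph = 0.5)
  traj <- simulate_experiment(
    pr, params, initial = init,
    light_fun = function(t) diel_irradiance(cfg, t),
    extra_source = function(t) cfg$h2s_supply_uM_s)

  gop_ref <- steady_state_rates(137, 0, params)$gop_e
  thr <- 0.05 * gop_ref
  t_h <- traj$times / 3600
  ap_on <- traj$gap_e > thr
  op_on <- traj$gop_e > thr
  win <- function(on) if (any(on)) range(t_h[on]) else c(NA_real_, NA_real_)
  lag <- NA_real_
  if (any(ap_on) && any(op_on)) {
    ap_end <- t_h[which(ap_on)]
    op_start <- t_h[which(op_on)[1]]
    ap_before <- ap_end[ap_end < op_start]
    if (length(ap_before)) lag <- (op_start - max(ap_before)) * 60
  }
  list(trajectory = traj,
       summary = list(ap_window = win(ap_on), op_window = win(op_on),
                      lag_minutes = lag))
}
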