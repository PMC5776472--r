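#' Experimental protocol for the simulated aquarium
#'
#' Describes a microsensor experiment on a biofilm in a stirred aquarium:
#' a piecewise-constant light schedule, sulfide injections into the water
#' column, an optional DCMU addition (treated as a binary PSII block from
#' that time on) and first-order exchange of H2S (outgassing) and O2 with
#' the ambient water.
#'
#' Injections are modelled as an exponentially mixed pulse: an injection of
#' `amount_uM` at time `t` with mixing time constant `tau_s` adds H2S to the
#' biofilm surface at rate `amount/tau * exp(-(t'-t)/tau)`.
#'
#' The pH channel of simulated traces is `ph_base` plus a small bounded
#' term (at most +/- 0.3 units) proportional to the smoothed photosynthetic
#' electron transport rate: enough to exercise sulfide speciation without
#' modelling carbonate chemistry.  Because the medium is pH-buffered,
#' biological consumption of total sulfide drains the H2S pool through the
#' speciation factor `1 + 10^(ph_base - pk1)`.
#'
#' @param duration experiment length (s).
#' @param light_schedule data.frame with columns `t_start` (s, strictly
#'   increasing, first row at 0) and `irradiance` (umol photons m-2 s-1).
#' @param injections data.frame with columns `t` (s), `amount_uM` (uM H2S
#'   added) and `tau_s` (mixing time constant, s); may have zero rows.
#' @param dcmu_at time (s) at which DCMU is added, or `NULL` for none.
#' @param h2s_outgassing_k first-order H2S loss constant (1/s).
#' @param o2_exchange_k first-order O2 exchange constant (1/s).
#' @param o2_ambient ambient O2 (uM).
#' @param h2s_clamp if not `NULL`, the local H2S is held at this value (uM)
#'   for the whole run (clamped boundary condition); injections and
#'   outgassing are ignored.
#' @param sampling_dt trace sampling interval (s).
#' @param ph_base,ph_coef,ph_tau baseline pH, pH response per unit electron
#'   transport rate (pH units per uM e-/s) and response time (s).
#' @param pk1 first dissociation constant of H2S used for the buffered
#'   speciation factor.
#' @return an `experiment_protocol` object (a validated list).
#' @examples
#' pr <- experiment_protocol(
#'   duration = 600,
#'   light_schedule = data.frame(t_start = 0, irradiance = 137),
#'   injections = data.frame(t = 60, amount_uM = 50, tau_s = 30))
#' @export
experiment_protocol <- function(duration,
                                light_schedule =
                                  data.frame(t_start = 0, irradiance = 0),
                                injections =
                                  data.frame(t = numeric(0),
                                             amount_uM = numeric(0),
                                             tau_s = numeric(0)),
                                dcmu_at = NULL,
                                h2s_outgassing_k = 5e-4,
                                o2_exchange_k = 5e-3,
                                o2_ambient = 0,
                                h2s_clamp = NULL,
                                sampling_dt = 0.25,
                                ph_base = 7.2, ph_coef = 0.005, ph_tau = 60,
                                pk1 = 6.98) {
  pr <- list(duration = duration, light_schedule = light_schedule,
             injections = injections, dcmu_at = dcmu_at,
             h2s_outgassing_k = h2s_outgassing_k,
             o2_exchange_k = o2_exchange_k, o2_ambient = o2_ambient,
             h2s_clamp = h2s_clamp, sampling_dt = sampling_dt,
             ph_base = ph_base, ph_coef = ph_coef, ph_tau = ph_tau,
             pk1 = pk1)
  class(pr) <- "experiment_protocol"
  validate_protocol(pr)
  pr
}

#' Validate an experiment protocol
#' @param pr an `experiment_protocol`.
#' @return `pr` invisibly, or an error.
#' @export
validate_protocol <- function(pr) {
  if (!inherits(pr, "experiment_protocol")) stop("not an experiment_protocol")
  if (!is.numeric(pr$duration) || pr$duration <= 0)
    stop("duration must be > 0")
  if (pr$sampling_dt <= 0) stop("sampling_dt must be > 0")
  ls <- pr$light_schedule
  if (!all(c("t_start", "irradiance") %in% names(ls)) || nrow(ls) < 1L)
    stop("light_schedule needs columns t_start, irradiance")
  if (ls$t_start[1] != 0) stop("light_schedule must start at t = 0")
  if (is.unsorted(ls$t_start, strictly = TRUE))
    stop("light_schedule times must be strictly increasing")
  if (any(ls$irradiance < 0)) stop("irradiance must be >= 0")
  inj <- pr$injections
  if (!all(c("t", "amount_uM", "tau_s") %in% names(inj)))
    stop("injections needs columns t, amount_uM, tau_s")
  if (nrow(inj) && (any(inj$amount_uM < 0) || any(inj$tau_s <= 0)))
    stop("injection amounts must be >= 0 and mixing constants > 0")
  if (nrow(inj) && is.unsorted(inj$t, strictly = TRUE))
    stop("injection times must be strictly increasing")
  if (pr$h2s_outgassing_k < 0 || pr$o2_exchange_k < 0)
    stop("exchange constants must be >= 0")
  if (!is.null(pr$h2s_clamp) && pr$h2s_clamp < 0)
    stop("h2s_clamp must be >= 0")
  invisible(pr)
}

# irradiance at time t (piecewise constant, right-continuous)
protocol_irradiance <- function(pr, t) {
  idx <- findInterval(t, pr$light_schedule$t_start)
  idx[idx < 1L] <- 1L
  pr$light_schedule$irradiance[idx]
}

#' Diel-cycle configuration
#'
#' Forcing for a lumped surface-layer diel simulation: irradiance follows a
#' half-sinusoid over the photoperiod (zero at night) and H2S is supplied
#' at a constant flux from below, balanced by outgassing and biological
#' consumption.
#'
#' @param photoperiod_h day length (h, <= 24).
#' @param peak_irradiance midday irradiance (umol photons m-2 s-1).
#' @param h2s_supply_uM_s constant H2S supply flux (uM/s).
#' @param duration_h simulated span (h); the photoperiod starts at t = 6 h
#'   of each 24 h cycle (dawn) so a 24 h run covers night-day-night.
#' @param h2s_outgassing_k first-order H2S loss (1/s).
#' @param sampling_dt trace sampling interval (s).
#' @return a `diel_config` object.
#' @export
diel_config <- function(photoperiod_h = 12, peak_irradiance = 200,
                        h2s_supply_uM_s = 2e-4, duration_h = 24,
                        h2s_outgassing_k = 1e-5, sampling_dt = 60) {
  if (photoperiod_h <= 0 || photoperiod_h > 24)
    stop("photoperiod_h must be in (0, 24]")
  if (peak_irradiance <= 0 || duration_h <= 0 || h2s_supply_uM_s < 0)
    stop("diel config values must be positive (supply flux >= 0)")
  cfg <- list(photoperiod_h = photoperiod_h,
              peak_irradiance = peak_irradiance,
              h2s_supply_uM_s = h2s_supply_uM_s,
              duration_h = duration_h,
              h2s_outgassing_k = h2s_outgassing_k,
              sampling_dt = sampling_dt)
  class(cfg) <- "diel_config"
  cfg
}

# diel irradiance (half-sinusoid between dawn = 6 h and dusk)
diel_irradiance <- function(cfg, t_s) {
  t_day <- (t_s / 3600) %% 24
  tt <- t_day - 6
  ifelse(tt > 0 & tt < cfg$photoperiod_h,
         cfg$peak_irradiance * sin(pi * tt / cfg$photoperiod_h), 0)
}
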