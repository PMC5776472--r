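#' Simulate a microsensor experiment
#'
#' Drives the electron transport model through an [experiment_protocol()]:
#' piecewise integration across light switches, injections and the DCMU
#' event with a stiff solver (rtol 1e-8, atol 1e-10), restarting exactly at
#' each event time.  Local H2S follows injection mixing, first-order
#' outgassing and biological consumption (through the buffered speciation
#' factor); O2 follows photosynthetic release and first-order exchange.
#'
#' @param protocol an [experiment_protocol()].
#' @param params a [model_params()] object.
#' @param initial initial state, default dark-adapted [model_state()].
#' @param light_fun optional function `f(t)` overriding the protocol's
#'   piecewise light schedule with a continuously varying irradiance (used
#'   for diel forcing).
#' @param extra_source optional function `f(t)` adding an H2S source flux
#'   (uM/s) on top of injections.
#' @return a `trajectory` object: list with `times` (s), `states` (matrix,
#'   one row per sample), `rates` (matrix of process rates), `gop_e`,
#'   `gap_e` (electron uM/s series), `irradiance`, `dcmu` (logical series),
#'   and `trace` (noise-free data.frame `time_s, o2_uM, h2s_uM, pH`).
#' @examples
#' pr <- experiment_protocol(duration = 60,
#'   light_schedule = data.frame(t_start = 0, irradiance = 137),
#'   sampling_dt = 1)
#' tr <- simulate_experiment(pr, model_params())
#' tail(tr$trace)
#' @export
simulate_experiment <- function(protocol, params, initial = model_state(),
                                light_fun = NULL, extra_source = NULL) {
  validate_protocol(protocol)
  validate_params(params)
  validate_state(initial)
  p <- params
  pr <- protocol
  clamp <- pr$h2s_clamp
  spec_f <- 1 + 10^(pr$ph_base - pr$pk1)

  s0 <- as.numeric(initial[state_names()])
  if (!is.null(clamp)) s0[13L] <- clamp

  inj <- pr$injections
  inj_source <- function(t) {
    if (!nrow(inj)) return(0)
    act <- inj$t <= t
    if (!any(act)) return(0)
    sum(inj$amount_uM[act] / inj$tau_s[act] *
          exp(-(t - inj$t[act]) / inj$tau_s[act]))
  }

  ev <- sort(unique(c(0, pr$light_schedule$t_start,
                      if (nrow(inj)) inj$t,
                      if (!is.null(pr$dcmu_at)) pr$dcmu_at,
                      pr$duration)))
  ev <- ev[ev >= 0 & ev <= pr$duration]
  samp <- seq(0, pr$duration, by = pr$sampling_dt)

  out_t <- numeric(0)
  out_s <- NULL
  s <- s0
  for (i in seq_len(length(ev) - 1L)) {
    t0 <- ev[i]; t1 <- ev[i + 1L]
    E_const <- if (is.null(light_fun)) protocol_irradiance(pr, t0) else NA
    dcmu_on <- !is.null(pr$dcmu_at) && t0 >= pr$dcmu_at
    deriv <- function(t, y, parms) {
      E <- if (is.null(light_fun)) E_const else light_fun(t)
      r <- .rates(y, E, p, dcmu_on)
      src <- inj_source(t) +
        (if (is.null(extra_source)) 0 else extra_source(t))
      d <- .derivs(y, r, p, list(h2s_source_rate = src,
                                 h2s_loss_k = pr$h2s_outgassing_k,
                                 o2_exchange_k = pr$o2_exchange_k,
                                 o2_ambient = pr$o2_ambient))
      # biological consumption drains buffered total sulfide
      cons <- (r[["k_AP"]] + r[["k_AP2"]]) / 2
      d[13L] <- d[13L] + cons - cons / spec_f
      if (!is.null(clamp)) d[13L] <- 0
      list(d)
    }
    times <- sort(unique(c(t0, samp[samp >= t0 & samp <= t1], t1)))
    sol <- deSolve::lsoda(y = s, times = times, func = deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("integrator failure in segment [%g, %g] (last time %g)",
                   t0, t1, max(sol[, 1])))
    s <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% samp & !(sol[, 1] %in% out_t)
    out_t <- c(out_t, sol[keep, 1])
    out_s <- rbind(out_s, sol[keep, -1, drop = FALSE])
  }

  colnames(out_s) <- state_names()
  n <- length(out_t)
  E_series <- if (is.null(light_fun)) protocol_irradiance(pr, out_t)
              else light_fun(out_t)
  dcmu_series <- if (is.null(pr$dcmu_at)) rep(FALSE, n)
                 else out_t >= pr$dcmu_at
  rates <- t(vapply(seq_len(n), function(i)
    as.numeric(.rates(out_s[i, ], E_series[i], p, dcmu_series[i])),
    numeric(12)))
  colnames(rates) <- c("k_L", "k_OP", "k_O2", "k_D", "k_R", "k_S1", "k_S2",
                       "k_AP", "k_AP2", "k_PQ", "k_PSI", "k_CO2")
  gop_e <- 4 * rates[, "k_O2"]
  gap_e <- rates[, "k_AP"] + rates[, "k_AP2"]

  ph <- .ph_channel(out_t, gop_e + gap_e, pr)
  # clip sub-tolerance integrator negatives; anything larger is a real error
  o2_tr <- out_s[, "o2"]; h2s_tr <- out_s[, "h2s"]
  o2_tr[o2_tr < 0 & o2_tr > -1e-7] <- 0
  h2s_tr[h2s_tr < 0 & h2s_tr > -1e-7] <- 0
  trace <- microsensor_trace(
    times = out_t, o2 = o2_tr, h2s = h2s_tr, ph = ph,
    meta = list(light_schedule = pr$light_schedule,
                event_times = ev, dcmu_at = pr$dcmu_at,
                pk1 = pr$pk1))

  traj <- list(times = out_t, states = out_s, rates = rates,
               gop_e = gop_e, gap_e = gap_e,
               irradiance = E_series, dcmu = dcmu_series,
               trace = trace, protocol = pr, params = p)
  class(traj) <- "trajectory"
  traj
}

# bounded, slowly responding pH channel: baseline plus a term proportional
# to the exponentially smoothed electron transport rate
.ph_channel <- function(times, activity, pr) {
  n <- length(times)
  sm <- numeric(n)
  if (n) sm[1] <- activity[1]
  for (i in seq_len(n - 1L)) {
    dt <- times[i + 1L] - times[i]
    a <- exp(-dt / pr$ph_tau)
    sm[i + 1L] <- a * sm[i] + (1 - a) * activity[i + 1L]
  }
  pr$ph_base + pmin(0.3, pmax(-0.3, pr$ph_coef * sm))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d samples over %.1f s; GOP_e in [%.3g, %.3g], GAP_e in [%.3g, %.3g] uM e-/s\n",
    length(x$times), max(x$times), min(x$gop_e), max(x$gop_e),
    min(x$gap_e), max(x$gap_e)))
  invisible(x)
}
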