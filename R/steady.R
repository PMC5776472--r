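#' Steady-state photosynthesis rates at clamped H2S
#'
#' Integrates the model at constant irradiance with the local H2S
#' concentration held fixed (clamped boundary condition) until the state
#' stops changing, then reports the gross oxygenic and anoxygenic electron
#' transport rates.  Convergence requires the maximum relative state change
#' to fall below `tol` per 100 s of simulated time; the horizon is doubled
#' until convergence or `max_time` is reached.
#'
#' @inheritParams rate_vector
#' @param h2s_clamped H2S concentration (uM) held constant.
#' @param init optional initial state; defaults to a dark-adapted state at
#'   the clamped H2S.
#' @param tol relative change per 100 s accepted as steady (default 1e-6).
#' @param max_time integration horizon cap (s).
#' @return list of class `"steady_rates"` with `gop_e`, `gap_e`
#'   (electron uM/s), the steady `state`, `converged` flag and
#'   `diagnostics` (horizon used, final relative change rate).
#' @examples
#' p <- model_params()
#' steady_state_rates(137, 0, p)$gop_e
#' @export
steady_state_rates <- function(irradiance, h2s_clamped, params,
                               dcmu = FALSE, init = NULL,
                               tol = 1e-6, max_time = 6e5) {
  validate_params(params)
  if (h2s_clamped < 0) stop("h2s_clamped must be >= 0")
  if (is.null(init)) {
    init <- model_state(h2s = h2s_clamped, nadph = 0.5)
  }
  s <- as.numeric(init[state_names()])
  s[13L] <- h2s_clamped

  deriv <- function(t, y, parms) {
    r <- .rates(y, irradiance, params, dcmu)
    d <- .derivs(y, r, params, .external_defaults(list()))
    d[13L] <- 0                       # clamp h2s
    list(d)
  }

  horizon <- 400
  t0 <- 0
  rel_change <- Inf
  repeat {
    sol <- deSolve::lsoda(y = s, times = c(0, horizon), func = deriv,
                          parms = NULL, rtol = 1e-8, atol = 1e-10,
                          maxsteps = 50000)
    s_new <- as.numeric(sol[nrow(sol), -1])
    # relative change per 100 s, judged on the pool states only (o2 and
    # the cumulative counters grow without bound when exchange is off)
    dyn <- 1:12
    rel_change <- max(abs(s_new[dyn] - s[dyn]) /
                        (abs(s_new[dyn]) + 1e-8)) * 100 / horizon
    s <- s_new
    t0 <- t0 + horizon
    if (rel_change < tol || t0 >= max_time) break
    horizon <- min(2 * horizon, max_time - t0)
  }

  names(s) <- state_names()
  r <- .rates(s, irradiance, params, dcmu)
  g <- gross_rates(r)
  out <- list(gop_e = unname(g["gop_e"]), gap_e = unname(g["gap_e"]),
              state = s, converged = rel_change < tol,
              diagnostics = list(time_integrated = t0,
                                 rel_change_per_100s = rel_change))
  if (!out$converged)
    warning(sprintf(
      "steady_state_rates: not converged within %g s (rel change %.3g)",
      t0, rel_change))
  class(out) <- "steady_rates"
  out
}

#' @export
print.steady_rates <- function(x, ...) {
  cat(sprintf("steady rates: GOP_e = %.4g, GAP_e = %.4g uM e-/s (%s)\n",
              x$gop_e, x$gap_e,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Steady anoxygenic rate with PSII blocked
#'
#' Steady-state gross anoxygenic electron transport at clamped H2S when
#' PSII contributes nothing (DCMU, or the fully H2S-inhibited OEC): only
#' the three redox carriers (PQ, the intermediate 'ET', NADP(H)) are
#' dynamic.  Their stationarity conditions collapse to a single equation
#' in the reduced PQ fraction, solved to near machine precision: from
#' `k_AP = k_PQ` the ET oxidation state follows, from `k_PSI = k_CO2` the
#' NADPH level follows, and the remaining flux balance through PSI is a
#' monotone function of `pq_red` with a sign change on the feasible
#' interval.  This is the model's own rate-law system solved exactly, not
#' a re-derived closed form; tests cross-check it against the full ODE
#' steady state and a brute-force fixed-step integration.
#'
#' @param E irradiance (umol photons m-2 s-1).
#' @param h2s clamped H2S (uM).
#' @param p a `model_params` object.
#' @return steady GAP_e (electron uM/s).
#' @keywords internal
.steady_gap <- function(E, h2s, p) {
  if (h2s <= 0) return(0)
  alpha <- if (p$variant == "A") 1 + p$alpha_amp * E / (p$K_alphaE + E) else 1
  gamma <- 1 + p$gamma_amp * h2s / (p$K_E + h2s)
  delta <- p$K_I / (p$K_I + h2s)
  vs <- p$v_sqr * alpha * h2s / (p$Km_sqr + h2s)
  vu <- if (p$variant == "B") p$v_uso * h2s / (p$Km_uso + h2s) else 0
  co2_cap <- p$v_co2 * gamma * delta

  total_flux <- function(pq) {
    k_AP <- vs * (1 - pq)
    et_ox <- if (pq > 0) min(k_AP / (p$k_pq * pq), 1) else 1
    k_AP + vu * et_ox
  }
  resid <- function(pq) {
    k_AP <- vs * (1 - pq)
    et_ox <- if (pq > 0) min(k_AP / (p$k_pq * pq), 1) else 1
    x <- k_AP + vu * et_ox          # flux PSI must carry
    n <- if (x >= co2_cap) 1 else
      min(p$K_nadph * x / (co2_cap - x), 1)
    p$f1 * (1 + p$beta * pq) * E * (1 - et_ox) * (1 - n) - x
  }
  if (vs + vu <= 0) return(0)
  # feasible interval: below pq_min the carrier downstream of PQ cannot
  # absorb the SQR flux (et_ox pinned at 1)
  pq_min <- vs / (p$k_pq + vs)
  lo <- max(pq_min, 1e-12); hi <- 1 - 1e-12
  if (resid(hi) <= 0) return(total_flux(hi))   # no PSI drain (e.g. dark)
  if (resid(lo) >= 0) return(total_flux(lo))
  root <- stats::uniroot(resid, c(lo, hi), tol = 1e-13)$root
  total_flux(root)
}

#' Steady anoxygenic photosynthesis rate under a PSII block
#'
#' User-facing wrapper around the blocked-PSII steady-state solver used
#' throughout the sulfide-response analyses: the steady gross anoxygenic
#' electron transport rate at clamped H2S under DCMU (or full OEC
#' inhibition), where only the redox carriers are dynamic.
#'
#' @param irradiance umol photons m-2 s-1.
#' @param h2s clamped H2S concentration (uM).
#' @param params a [model_params()] object.
#' @return steady GAP_e (electron uM/s).
#' @examples
#' steady_anoxygenic_rate(137, 44, model_params())
#' @export
steady_anoxygenic_rate <- function(irradiance, h2s, params) {
  validate_params(params)
  if (irradiance < 0 || h2s < 0)
    stop("irradiance and h2s must be >= 0")
  .steady_gap(irradiance, h2s, params)
}
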