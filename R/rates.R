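#' Process rates of the redox reaction network
#'
#' Evaluates every process rate of the electron transport network at a given
#' state and irradiance.  Electron-transport steps (`k_OP`, `k_AP`, `k_AP2`,
#' `k_PQ`, `k_PSI`, `k_CO2`) are in electron-equivalent uM/s; the pure
#' pool-state transitions (`k_L`, `k_D`, `k_R`, `k_S1`, `k_S2`) are in
#' pool-fraction/s; `k_O2` is the O2 release rate in uM O2/s (one O2 per
#' four water-derived electrons).
#'
#' Rate laws (minimal mass-action / Michaelis forms):
#' \itemize{
#'   \item `k_L  = f2 * E * psii_g` - PSII excitation.
#'   \item `k_OP = k_op_cat * psii_e * oec_a * pq_ox` - PQ reduction by
#'     PSII (oxygenic electron transport); zero under DCMU.
#'   \item `k_O2 = k_o2 * oec_ox * oec_tot / 4` - O2 release.
#'   \item `k_D  = k_d_max * psii_e * E / (K_dE + E)` - photoinhibition,
#'     saturating at high light.
#'   \item `k_R  = k_r * psii_d` - PSII repair.
#'   \item `k_S1 = k_s1 * oec_ox * h2s` - OEC intermediate inhibition by H2S.
#'   \item `k_S2 = k_s2 * oec_i` - deinhibition.
#'   \item `k_AP = v_sqr * alpha * h2s/(Km_sqr + h2s) * pq_ox` - sulfide
#'     oxidation by SQR reducing PQ, with
#'     `alpha = 1 + alpha_amp * E/(K_alphaE + E)` under variant "A" and
#'     `alpha = 1` under variant "B".
#'   \item `k_AP2 = v_uso * h2s/(Km_uso + h2s) * et_ox` - sulfide oxidation
#'     by the USO reducing the carrier downstream of PQ (variant "B" only;
#'     zero under variant "A").
#'   \item `k_PQ  = k_pq * pq_red * et_ox` - PQ reoxidation.
#'   \item `k_PSI = f1 * (1 + beta*pq_red) * E * et_red * nadp` - PSI
#'     turnover, boosted by excitation transfer from PSII.
#'   \item `k_CO2 = v_co2 * gamma * delta * nadph/(K_nadph + nadph)` - CO2
#'     fixation (NADPH sink), with the H2S enhancement
#'     `gamma = 1 + gamma_amp*h2s/(K_E + h2s)` and inhibition
#'     `delta = K_I/(K_I + h2s)`.
#' }
#'
#' @param state a valid model state (see [model_state()]).
#' @param irradiance incident photon flux E (umol photons m-2 s-1, >= 0).
#' @param params a [model_params()] object.
#' @param dcmu logical; if `TRUE` the PSII-to-PQ step is blocked
#'   (`k_OP = 0`) while excitation, photoinhibition and repair stay active.
#' @return named numeric vector of class `"rate_vector"` with components
#'   `k_L, k_OP, k_O2, k_D, k_R, k_S1, k_S2, k_AP, k_AP2, k_PQ, k_PSI,
#'   k_CO2`, plus attributes `alpha`, `gamma`, `delta`.
#' @examples
#' p <- model_params()
#' s <- model_state(psii_g = 0.9, psii_e = 0.1, h2s = 20)
#' rate_vector(s, irradiance = 137, p)
#' @export
rate_vector <- function(state, irradiance, params, dcmu = FALSE) {
  validate_state(state, tol = 1e-6)
  validate_params(params)
  if (!is.numeric(irradiance) || length(irradiance) != 1L ||
      !is.finite(irradiance) || irradiance < 0)
    stop("irradiance must be a single non-negative number")
  r <- .rates(as.numeric(state[state_names()]), irradiance, params,
              isTRUE(dcmu))
  class(r) <- "rate_vector"
  r
}

# fast internal kernel: s is the plain numeric state in state_names() order
.rates <- function(s, E, p, dcmu) {
  s <- unname(s)
  psii_g <- s[1L]; psii_e <- s[2L]; psii_d <- s[3L]
  oec_a <- s[4L]; oec_ox <- s[5L]; oec_i <- s[6L]
  pq_ox <- s[7L]; pq_red <- s[8L]
  et_ox <- s[9L]; et_red <- s[10L]
  nadp <- s[11L]; nadph <- s[12L]
  h2s <- max(s[13L], 0)

  alpha <- if (p$variant == "A") 1 + p$alpha_amp * E / (p$K_alphaE + E) else 1
  gamma <- 1 + p$gamma_amp * h2s / (p$K_E + h2s)
  delta <- p$K_I / (p$K_I + h2s)

  k_L  <- p$f2 * E * psii_g
  k_OP <- if (dcmu) 0 else p$k_op_cat * psii_e * oec_a * pq_ox
  k_O2 <- p$k_o2 * oec_ox * p$oec_tot / 4
  k_D  <- p$k_d_max * psii_e * E / (p$K_dE + E)
  k_R  <- p$k_r * psii_d
  k_S1 <- p$k_s1 * oec_ox * h2s
  k_S2 <- p$k_s2 * oec_i
  k_AP <- p$v_sqr * alpha * h2s / (p$Km_sqr + h2s) * pq_ox
  k_AP2 <- if (p$variant == "B")
    p$v_uso * h2s / (p$Km_uso + h2s) * et_ox else 0
  k_PQ  <- p$k_pq * pq_red * et_ox
  k_PSI <- p$f1 * (1 + p$beta * pq_red) * E * et_red * nadp
  k_CO2 <- p$v_co2 * gamma * delta * nadph / (p$K_nadph + nadph)

  out <- c(k_L = k_L, k_OP = k_OP, k_O2 = k_O2, k_D = k_D, k_R = k_R,
           k_S1 = k_S1, k_S2 = k_S2, k_AP = k_AP, k_AP2 = k_AP2,
           k_PQ = k_PQ, k_PSI = k_PSI, k_CO2 = k_CO2)
  attr(out, "alpha") <- alpha
  attr(out, "gamma") <- gamma
  attr(out, "delta") <- delta
  out
}

#' Time derivative of the model state
#'
#' Wires the process rates of [rate_vector()] into the stoichiometry of the
#' network.  Electron fluxes (uM e-/s) move pool fractions at
#' `flux / pool_tot`; the PSII/OEC catalytic cycle turns over at
#' `k_OP / psii_tot` resp. `k_OP / oec_tot` per second.  H2S is consumed at
#' half the anoxygenic electron flux (2 e- per sulfide, yielding zero-valent
#' sulfur), O2 is released at one quarter of the water-derived electron flux
#' and CO2 fixation consumes 4 electron-equivalents (2 NADPH) per carbon.
#' Every conserved pool sum has derivative exactly zero by construction.
#'
#' @inheritParams rate_vector
#' @param external list with optional first-order exchange terms:
#'   `h2s_source_rate` (uM/s added to local H2S), `h2s_loss_k` (1/s,
#'   outgassing), `o2_exchange_k` (1/s) and `o2_ambient` (uM).
#' @return named numeric vector `d(state)/dt` in the order of the state.
#' @export
state_derivative <- function(state, irradiance, params, dcmu = FALSE,
                             external = list()) {
  validate_state(state, tol = 1e-6)
  ext <- .external_defaults(external)
  if (any(!is.finite(unlist(ext)))) stop("external terms must be finite")
  r <- rate_vector(state, irradiance, params, dcmu)
  .derivs(as.numeric(state[state_names()]), r, params, ext)
}

.external_defaults <- function(external) {
  ext <- list(h2s_source_rate = 0, h2s_loss_k = 0,
              o2_exchange_k = 0, o2_ambient = 0)
  ext[names(external)] <- external
  ext
}

# stoichiometric wiring; r is a rate vector from .rates()
.derivs <- function(s, r, p, ext) {
  turn_psii <- r[["k_OP"]] / p$psii_tot
  turn_oec  <- r[["k_OP"]] / p$oec_tot
  relax_oec <- 4 * r[["k_O2"]] / p$oec_tot   # fraction/s

  # freeze states that have decayed to numerical zero: pure exponential
  # decay (e.g. NADPH in darkness) otherwise underflows to denormals and
  # stalls the integrator; applied before the closure members are formed
  # so pool conservation stays exact
  frz <- function(y, d) if (y < 1e-14 && d < 0) 0 else d

  d_psii_e <- frz(s[2L], r[["k_L"]] - r[["k_D"]] - turn_psii)
  d_psii_d <- frz(s[3L], r[["k_D"]] - r[["k_R"]])
  d_psii_g <- -(d_psii_e + d_psii_d)     # conservation exact in float

  d_oec_ox <- frz(s[5L], turn_oec - relax_oec - r[["k_S1"]] + r[["k_S2"]])
  d_oec_i  <- frz(s[6L], r[["k_S1"]] - r[["k_S2"]])
  d_oec_a  <- -(d_oec_ox + d_oec_i)

  d_pq_red <- frz(s[8L],
                  (r[["k_OP"]] + r[["k_AP"]] - r[["k_PQ"]]) / p$pq_tot)
  d_et_red <- frz(s[10L],
                  (r[["k_PQ"]] + r[["k_AP2"]] - r[["k_PSI"]]) / p$et_tot)
  d_nadph  <- frz(s[12L], (r[["k_PSI"]] - r[["k_CO2"]]) / p$nadp_tot)

  cons <- (r[["k_AP"]] + r[["k_AP2"]]) / 2
  d_h2s <- frz(s[13L],
               -cons + ext$h2s_source_rate -
                 ext$h2s_loss_k * max(s[13L], 0))
  d_o2  <- frz(s[14L],
               r[["k_O2"]] + ext$o2_exchange_k * (ext$o2_ambient - s[14L]))

  c(psii_g = d_psii_g, psii_e = d_psii_e, psii_d = d_psii_d,
    oec_a = d_oec_a, oec_ox = d_oec_ox, oec_i = d_oec_i,
    pq_ox = -d_pq_red, pq_red = d_pq_red,
    et_ox = -d_et_red, et_red = d_et_red,
    nadp = -d_nadph, nadph = d_nadph,
    h2s = d_h2s, o2 = d_o2,
    s0_cum = cons, c_fix_cum = r[["k_CO2"]] / 4)
}

#' Instantaneous gross photosynthesis rates from a rate vector
#'
#' `GOP_e = 4 * k_O2` (oxygenic, electron equivalents of O2 release) and
#' `GAP_e = k_AP + k_AP2` (anoxygenic, equal to twice the sulfide
#' consumption rate).
#'
#' @param r a `rate_vector`.
#' @return named numeric `c(gop_e, gap_e)` in electron uM/s.
#' @export
gross_rates <- function(r) {
  c(gop_e = 4 * r[["k_O2"]], gap_e = r[["k_AP"]] + r[["k_AP2"]])
}
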