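#' Model state vector
#'
#' The state of the electron transport model is a named numeric vector with
#' five conserved fractional pools plus local chemistry and two cumulative
#' bookkeeping quantities:
#' \describe{
#'   \item{psii_g, psii_e, psii_d}{photosystem II in ground, excited and
#'     degraded/inactive state (fractions summing to 1).}
#'   \item{oec_a, oec_ox, oec_i}{oxygen-evolving complex: active, reactive
#'     intermediate formed during water oxidation, and H2S-inhibited
#'     (fractions summing to 1).}
#'   \item{pq_ox, pq_red}{oxidized / reduced plastoquinone pool fractions.}
#'   \item{et_ox, et_red}{oxidized / reduced fractions of the intermediate
#'     electron carrier between PQ and PSI.}
#'   \item{nadp, nadph}{oxidized / reduced NADP pool fractions.}
#'   \item{h2s, o2}{local concentrations at the biofilm surface (uM).}
#'   \item{s0_cum, c_fix_cum}{cumulative zero-valent sulfur produced and
#'     CO2 fixed (uM equivalents), non-decreasing along a trajectory.}
#' }
#'
#' @param psii_g,psii_e,psii_d PSII state fractions.
#' @param oec_a,oec_ox,oec_i OEC state fractions.
#' @param pq_red,et_red,nadph reduced fractions of the redox carriers (the
#'   oxidized fractions are set to the complements).
#' @param h2s,o2 local H2S and O2 (uM).
#' @param s0_cum,c_fix_cum cumulative S0 and fixed C (uM equivalents).
#' @return named numeric vector of class `"model_state"`.
#' @examples
#' s <- model_state()        # dark-adapted resting state
#' sum(s[c("psii_g", "psii_e", "psii_d")])
#' @export
model_state <- function(psii_g = 1, psii_e = 0, psii_d = 0,
                        oec_a = 1, oec_ox = 0, oec_i = 0,
                        pq_red = 0, et_red = 0, nadph = 0.5,
                        h2s = 0, o2 = 0, s0_cum = 0, c_fix_cum = 0) {
  s <- c(psii_g = psii_g, psii_e = psii_e, psii_d = psii_d,
         oec_a = oec_a, oec_ox = oec_ox, oec_i = oec_i,
         pq_ox = 1 - pq_red, pq_red = pq_red,
         et_ox = 1 - et_red, et_red = et_red,
         nadp = 1 - nadph, nadph = nadph,
         h2s = h2s, o2 = o2, s0_cum = s0_cum, c_fix_cum = c_fix_cum)
  class(s) <- "model_state"
  validate_state(s)
  s
}

state_names <- function() {
  c("psii_g", "psii_e", "psii_d", "oec_a", "oec_ox", "oec_i",
    "pq_ox", "pq_red", "et_ox", "et_red", "nadp", "nadph",
    "h2s", "o2", "s0_cum", "c_fix_cum")
}

#' Validate a model state
#'
#' Checks that every pool fraction lies in \[0, 1\], that the five conserved
#' pool sums equal 1 within `tol`, and that concentrations are non-negative.
#'
#' @param s a state vector (named as in [model_state()]).
#' @param tol tolerance on the pool sums (default 1e-8, loosened slightly
#'   for integrator output via `tol = 1e-6` where appropriate).
#' @return `s` invisibly if valid, otherwise an error.
#' @export
validate_state <- function(s, tol = 1e-8) {
  nm <- state_names()
  if (!all(nm %in% names(s)))
    stop("state is missing components: ",
         paste(setdiff(nm, names(s)), collapse = ", "))
  s <- s[nm]
  frac <- s[1:12]
  if (any(!is.finite(s))) stop("non-finite state component")
  if (any(frac < -tol) || any(frac > 1 + tol))
    stop("pool fraction outside [0, 1]")
  sums <- c(psii = sum(s[c("psii_g", "psii_e", "psii_d")]),
            oec  = sum(s[c("oec_a", "oec_ox", "oec_i")]),
            pq   = sum(s[c("pq_ox", "pq_red")]),
            et   = sum(s[c("et_ox", "et_red")]),
            nadp = sum(s[c("nadp", "nadph")]))
  bad <- abs(sums - 1) > tol
  if (any(bad))
    stop("conserved pool sum(s) differ from 1 beyond tolerance: ",
         paste(names(sums)[bad], collapse = ", "))
  if (s["h2s"] < -tol || s["o2"] < -tol)
    stop("negative concentration in state")
  invisible(s)
}

#' Electron content of the redox pools
#'
#' Sums the electron-equivalents (uM) currently stored in the reduced
#' carriers (PQ_red, ET_red, NADPH) minus the oxidizing holes held by the
#' OEC intermediate and its H2S-inhibited form.  The OEC terms are negative
#' because water-derived electrons are passed to PQ when the intermediate
#' forms, while the corresponding O2 is only released on relaxation; until
#' then the pool carries a hole.  With external exchange disabled this
#' quantity closes the electron balance
#' `2*dS_consumed + 4*dO2_produced = 4*dC_fixed + d(content)` exactly.
#'
#' @param s state vector.
#' @param p `model_params` (pool capacities).
#' @return electron content in uM electron equivalents.
#' @export
electron_content <- function(s, p) {
  unname(s["pq_red"] * p$pq_tot + s["et_red"] * p$et_tot +
           s["nadph"] * p$nadp_tot -
           (s["oec_ox"] + s["oec_i"]) * p$oec_tot)
}

#' @export
print.model_state <- function(x, ...) {
  cat("Model state\n")
  print(unclass(x))
  invisible(x)
}
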