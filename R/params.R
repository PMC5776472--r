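#' Kinetic parameters of the electron transport model
#'
#' Constructs the full parameter set of the photosynthetic electron transport
#' model: photosystem II (PSII) excitation, photoinhibition and repair,
#' sulfide inhibition of the oxygen-evolving complex (OEC), sulfide oxidation
#' feeding the plastoquinone (PQ) pool and (variant "B") an intermediate
#' carrier downstream of PQ, PSI turnover and NADPH-consuming CO2 fixation.
#'
#' Two model variants are supported, differing in how the light dependence of
#' anoxygenic photosynthesis is generated:
#' \describe{
#'   \item{"A"}{a single sulfide:quinone oxidoreductase (SQR) whose maximum
#'     rate is scaled by a light-activation factor
#'     \eqn{\alpha = 1 + \alpha_{amp} E/(K_{\alpha E}+E)}.}
#'   \item{"B"}{two sulfide-oxidizing enzymes: an SQR reducing the PQ pool
#'     plus an unidentified sulfide oxidase (USO) donating electrons to the
#'     intermediate carrier 'ET' downstream of PQ (e.g. cytochrome b6f or
#'     plastocyanin); no direct light effect on either enzyme.}
#' }
#' The single-enzyme null model (no light activation, no USO) is obtained by
#' setting `alpha_amp = 0` under variant "A" (or `v_uso = 0` under "B").
#'
#' Electron transport rates are expressed in electron-equivalent uM/s.
#' Conserved pools (PSII states, OEC states, PQ, ET, NADP(H)) are fractions
#' of a fixed total; the `*_tot` capacities give each pool's size in
#' electron-equivalent uM and couple fraction turnover to electron flux.
#'
#' @param variant `"A"` (light-regulated SQR) or `"B"` (SQR + USO).
#' @param f2,f1 absorbance cross-section factors of PSII and PSI: lumped
#'   conversion from incident photon flux E (umol photons m-2 s-1) to
#'   volumetric excitation (per s per unit E).
#' @param beta PSII-to-PSI excitation transfer amplitude (dimensionless);
#'   PSI turnover carries the factor `(1 + beta * pq_red)`.
#' @param k_op_cat PSII-to-PQ catalytic constant (electron uM/s at full
#'   occupancy of PSII*, active OEC and oxidized PQ).
#' @param k_o2 O2-release (OEC_ox relaxation) constant (1/s).
#' @param k_d_max,K_dE photoinhibition maximum rate (1/s) and light
#'   half-saturation (umol photons m-2 s-1); the degradation rate saturates
#'   at high light.
#' @param k_r PSII repair constant (1/s).
#' @param k_s1 OEC_ox + H2S binding constant (1/(uM s)).
#' @param k_s2 OEC deinhibition (H2S release) constant (1/s).
#' @param v_sqr,Km_sqr SQR maximum rate (electron uM/s) and Michaelis
#'   constant for H2S (uM).
#' @param alpha_amp,K_alphaE light activation of SQR (variant "A" only):
#'   amplitude (dimensionless) and half-saturation (umol photons m-2 s-1).
#' @param v_uso,Km_uso USO maximum rate (electron uM/s) and Michaelis
#'   constant (uM); variant "B" only.
#' @param k_pq PQ_red -> ET electron transfer constant (electron uM/s at
#'   full occupancy).
#' @param v_co2,K_nadph CO2-fixation maximum rate (electron uM/s) and NADPH
#'   half-saturation (fraction of the NADP pool).
#' @param gamma_amp,K_E H2S enhancement of CO2 fixation: amplitude and
#'   half-saturation (uM); the enhancement factor is
#'   \eqn{\gamma = 1 + \gamma_{amp}[H_2S]/(K_E+[H_2S])}.
#' @param K_I H2S inhibition constant of CO2 fixation (uM); the inhibition
#'   factor is \eqn{\delta = K_I/(K_I+[H_2S])}.  `K_E < K_I` is required so
#'   enhancement precedes inhibition as H2S rises.
#' @param psii_tot,oec_tot,pq_tot,et_tot,nadp_tot pool capacities in
#'   electron-equivalent uM.
#'
#' @return An object of class `"model_params"` (a named list).
#' @examples
#' p <- model_params()
#' p$Km_sqr
#' pA <- model_params(variant = "A")
#' @export
model_params <- function(variant = c("B", "A"),
                         f2 = 0.0557,
                         k_op_cat = 12,
                         k_o2 = 10,
                         k_d_max = 3.4e-3,
                         K_dE = 800,
                         k_r = 1e-4,
                         k_s1 = 0.02,
                         k_s2 = 1.55e-5,
                         v_sqr = 4.0,
                         Km_sqr = 100,
                         alpha_amp = 4,
                         K_alphaE = 100,
                         v_uso = 3.92,
                         Km_uso = 4.46,
                         k_pq = 16.7,
                         f1 = 0.0155,
                         beta = 0.349,
                         v_co2 = 1.123,
                         K_nadph = 0.084,
                         gamma_amp = 2.44,
                         K_E = 6.85,
                         K_I = 73.6,
                         psii_tot = 0.3,
                         oec_tot = 0.3,
                         pq_tot = 0.4,
                         et_tot = 0.2,
                         nadp_tot = 0.4) {
  variant <- match.arg(variant)
  p <- list(variant = variant,
            f2 = f2, k_op_cat = k_op_cat, k_o2 = k_o2,
            k_d_max = k_d_max, K_dE = K_dE, k_r = k_r,
            k_s1 = k_s1, k_s2 = k_s2,
            v_sqr = v_sqr, Km_sqr = Km_sqr,
            alpha_amp = alpha_amp, K_alphaE = K_alphaE,
            v_uso = v_uso, Km_uso = Km_uso,
            k_pq = k_pq, f1 = f1, beta = beta,
            v_co2 = v_co2, K_nadph = K_nadph,
            gamma_amp = gamma_amp, K_E = K_E, K_I = K_I,
            psii_tot = psii_tot, oec_tot = oec_tot, pq_tot = pq_tot,
            et_tot = et_tot, nadp_tot = nadp_tot)
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a model parameter set
#'
#' Checks positivity of all rate and affinity constants, the variant switch,
#' and the ordering `K_E < K_I` (enhancement of CO2 fixation by H2S must
#' saturate before inhibition takes over).
#'
#' @param p a `model_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  if (!inherits(p, "model_params"))
    stop("not a 'model_params' object")
  if (!p$variant %in% c("A", "B"))
    stop("variant must be \"A\" or \"B\"")
  pos <- setdiff(names(p), c("variant", "beta", "alpha_amp", "gamma_amp",
                             "v_uso", "v_sqr", "k_d_max"))
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be a positive finite scalar", nm))
  for (nm in c("beta", "alpha_amp", "gamma_amp", "v_uso", "v_sqr", "k_d_max"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop(sprintf("parameter '%s' must be a non-negative finite scalar", nm))
  if (p$K_E >= p$K_I)
    stop("K_E must be smaller than K_I (enhancement before inhibition)")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Electron transport model parameters (variant ", x$variant, ")\n",
      sep = "")
  num <- unlist(x[setdiff(names(x), "variant")])
  print(num)
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named parameters replaced, re-validated.
#'
#' @param p a `model_params` object.
#' @param ... named replacements, e.g. `update_params(p, Km_sqr = 50)`.
#'   `variant` may be changed too.
#' @return a new `model_params` object.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(p)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("all replacements must be named")
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- repl
  validate_params(p)
  p
}

#' Read / write model parameters as a YAML config
#'
#' The config is a flat typed mapping, one key per parameter; `variant` is a
#' string, everything else numeric.  Unknown keys are rejected so typos do
#' not silently fall back to defaults.
#'
#' @param path file path.
#' @return `read_params()` returns a `model_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("malformed params config: ", path)
  do.call(model_params, raw)
}

#' @rdname read_params
#' @param p a `model_params` object to serialize.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}
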