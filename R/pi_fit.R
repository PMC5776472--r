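#' Fit a photosynthesis-irradiance curve
#'
#' Fits the three-parameter PI model with photoinhibition,
#' \deqn{P(E) = E / (a E^2 + b E + c),}
#' to extracted GOP points by nonlinear least squares.  The optimal
#' irradiance is `e_opt = sqrt(c/a)` and the maximum rate
#' `p_max = 1/(b + 2*sqrt(a*c))`.  Initialization is deterministic: since
#' `E/P` is linear in `(E^2, E, 1)`, an ordinary linear regression of
#' `E/P` on `E^2` and `E` provides the starting values, refined with
#' [minpack.lm::nlsLM] on the original scale.
#'
#' @param points a `rate_point` data.frame with GOP rows (`irradiance`,
#'   `rate_e`); at least 4 distinct positive irradiances are required, and
#'   the apparent optimum (largest observed rate) must not sit at the
#'   largest irradiance, so that the declining limb is represented.
#' @return object of class `pi_curve_fit`: list with coefficients `a`,
#'   `b`, `c`, derived `e_opt` and `p_max`, and `residual_ss`.
#' @examples
#' E <- c(10, 30, 60, 100, 137, 180, 250)
#' P <- E / ((1/137^2) * E^2 + 0.2 * E + 1)
#' fit_pi_curve(data.frame(irradiance = E, rate_e = P))
#' @export
fit_pi_curve <- function(points) {
  E <- points$irradiance
  P <- points$rate_e
  keep <- E > 0 & is.finite(P) & P > 0
  E <- E[keep]; P <- P[keep]
  if (length(unique(E)) < 4L)
    stop("need at least 4 distinct positive irradiances")
  if (E[which.max(P)] >= max(E))
    stop("no irradiance above the apparent optimum; cannot constrain the ",
         "declining limb")
  z <- E / P
  lin <- stats::lm(z ~ I(E^2) + E)
  init <- stats::coef(lin)
  c0 <- max(init[["(Intercept)"]], 1e-10)
  a0 <- init[["I(E^2)"]]
  if (!is.finite(a0) || a0 <= 0) a0 <- c0 / max(E)^2  # optimum at grid edge
  b0 <- init[["E"]]
  # parameters kept on log scale for a (and c) so the Jacobian is well
  # conditioned despite the ~1e5 scale separation between a and c
  resid_fn <- function(th)
    P - E / (exp(th[1]) * E^2 + th[2] * E + exp(th[3]))
  fit <- minpack.lm::nls.lm(
    par = c(log(a0), b0, log(c0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info < 1 || fit$info > 4)
    stop("PI-curve fit did not converge (info = ", fit$info,
         "); initialization: a0 = ", signif(a0, 4), ", b0 = ",
         signif(b0, 4), ", c0 = ", signif(c0, 4))
  a <- exp(fit$par[1]); b <- fit$par[2]; cc <- exp(fit$par[3])
  out <- list(a = a, b = b, c = cc,
              e_opt = sqrt(cc / a),
              p_max = 1 / (b + 2 * sqrt(a * cc)),
              residual_ss = sum(resid_fn(fit$par)^2),
              n = length(E))
  class(out) <- "pi_curve_fit"
  out
}

#' @export
print.pi_curve_fit <- function(x, ...) {
  cat(sprintf(
    "PI-curve fit: e_opt = %.1f umol photons m-2 s-1, p_max = %.4g uM e-/s (SS = %.3g, n = %d)\n",
    x$e_opt, x$p_max, x$residual_ss, x$n))
  invisible(x)
}
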