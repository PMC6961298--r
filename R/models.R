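#' Forward diffusion signal models
#'
#' Noiseless signal equations for the three decay models used throughout:
#' mono-exponential (Gaussian diffusion), intravoxel incoherent motion
#' (IVIM, bi-exponential) and the stretched-exponential model (SEM).
#' These are the single source of truth shared by the fitters and the
#' phantom simulator.
#'
#' The models, with S0 the signal at b = 0:
#' \describe{
#'   \item{mono}{S(b) = S0 exp(-b ADC)}
#'   \item{IVIM}{S(b) = S0 \[(1 - f) exp(-b D) + f exp(-b (D + D*))\]}
#'   \item{SEM}{S(b) = S0 exp(-(b DDC)^alpha)}
#' }
#' D is the slow (true) diffusion coefficient, D* the pseudo-diffusion
#' coefficient of capillary microcirculation and f the perfusion fraction.
#' DDC is the distributed diffusion coefficient and alpha in (0, 1] the
#' intravoxel heterogeneity index; alpha = 1 recovers Gaussian diffusion.
#' All diffusivities are in mm^2/s and b in s/mm^2.
#'
#' @param b Diffusion weighting(s), s/mm^2, non-negative (vectorized).
#' @param s0 Signal at b = 0, arbitrary units, > 0.
#' @param adc Apparent diffusion coefficient, mm^2/s, > 0.
#' @return Numeric vector of signal values, same length as `b`.
#' @examples
#' b <- default_bvalue_scheme()$b_values
#' signal_mono(b, s0 = 1, adc = 0.619e-3)
#' signal_sem(b, s0 = 1, ddc = 0.972e-3, alpha = 0.910)
#' @export
signal_mono <- function(b, s0, adc) {
  check_b(b)
  if (!is.finite(s0) || s0 <= 0) stopf("s0 must be > 0")
  if (!is.finite(adc) || adc <= 0) stopf("adc must be > 0")
  s0 * exp(-b * adc)
}

#' @rdname signal_mono
#' @param d Slow/true diffusion coefficient D, mm^2/s, > 0.
#' @param d_star Pseudo-diffusion coefficient D*, mm^2/s, > 0.
#' @param f Perfusion fraction, in \[0, 1\].
#' @param pseudo_exponent Decay rate of the perfusion compartment:
#'   `"d_plus_dstar"` (default) uses exp(-b (D + D*)); `"dstar"` uses the
#'   also-common exp(-b D*).
#' @export
signal_ivim <- function(b, s0, d, d_star, f,
                        pseudo_exponent = c("d_plus_dstar", "dstar")) {
  pseudo_exponent <- match.arg(pseudo_exponent)
  check_b(b)
  if (!is.finite(s0) || s0 <= 0) stopf("s0 must be > 0")
  if (!is.finite(d) || d <= 0) stopf("d must be > 0")
  if (!is.finite(d_star) || d_star <= 0) stopf("d_star must be > 0")
  if (!is.finite(f) || f < 0 || f > 1) stopf("f must be in [0, 1]")
  rate <- if (pseudo_exponent == "d_plus_dstar") d + d_star else d_star
  s0 * ((1 - f) * exp(-b * d) + f * exp(-b * rate))
}

#' @rdname signal_mono
#' @param ddc Distributed diffusion coefficient, mm^2/s, > 0.
#' @param alpha Heterogeneity index, in (0, 1].
#' @export
signal_sem <- function(b, s0, ddc, alpha) {
  check_b(b)
  if (!is.finite(s0) || s0 <= 0) stopf("s0 must be > 0")
  if (!is.finite(ddc) || ddc <= 0) stopf("ddc must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stopf("alpha must be in (0, 1]")
  s0 * exp(-(b * ddc)^alpha)
}

check_b <- function(b) {
  if (!is.numeric(b) || any(!is.finite(b)) || any(b < 0))
    stopf("b must be finite and >= 0")
  invisible(b)
}
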