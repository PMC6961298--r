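`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x == round(x))

#' Convert diffusion parameters between internal and reporting units
#'
#' Internally every diffusivity (ADC, D, D*, DDC) is carried in mm^2/s and
#' the perfusion fraction f as a proportion in \[0, 1\]. Reports and the
#' cohort tables use the conventional scale: diffusivities in
#' 10^-3 mm^2/s and f in percent. alpha is unitless on both scales.
#'
#' @param params Named numeric vector or data frame with any of the columns
#'   `adc`, `d`, `d_star`, `ddc`, `f`, `alpha`, `s0`.
#' @return Object of the same shape with units converted.
#' @export
to_reporting_units <- function(params) {
  scale_params(params, diff_factor = 1e3, f_factor = 1e2)
}

#' @rdname to_reporting_units
#' @export
to_internal_units <- function(params) {
  scale_params(params, diff_factor = 1e-3, f_factor = 1e-2)
}

scale_params <- function(params, diff_factor, f_factor) {
  nm <- if (is.data.frame(params)) names(params) else names(params)
  if (is.null(nm)) stopf("parameters must be named")
  diffusive <- intersect(nm, c("adc", "d", "d_star", "ddc"))
  for (p in diffusive) {
    if (is.data.frame(params)) params[[p]] <- params[[p]] * diff_factor
    else params[p] <- params[p] * diff_factor
  }
  if ("f" %in% nm) {
    if (is.data.frame(params)) params[["f"]] <- params[["f"]] * f_factor
    else params["f"] <- params["f"] * f_factor
  }
  params
}
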