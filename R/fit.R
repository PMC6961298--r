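#' Default box bounds for the voxel fitters
#'
#' Physiologic ranges wide enough to cover reported tumor values by many
#' standard deviations. Diffusivities in mm^2/s. `d_star_delta` bounds the
#' excess of D* over D (the fitters parameterize D* = D + delta), which
#' keeps the slow and pseudo-diffusion components from swapping labels.
#'
#' @return Named list of length-2 numeric ranges.
#' @export
default_fit_bounds <- function() {
  list(adc   = c(1e-5, 5e-3),
       d     = c(1e-5, 5e-3),
       ddc   = c(1e-5, 5e-3),
       d_star_delta = c(0, 0.1),
       f     = c(0, 1),
       alpha = c(0.01, 1))
}

model_fit <- function(model, params, values, fitted, converged, status) {
  r2 <- if (all(is.finite(fitted))) goodness_of_fit(values, fitted) else NA_real_
  structure(list(model = model, params = params, r_squared = r2,
                 converged = converged, status = status, fitted = fitted),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<%s fit>  converged: %s  status: %s  R^2: %s\n",
              x$model, x$converged, x$status,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  pr <- unlist(x$params)
  cat(" ", paste(sprintf("%s = %.6g", names(pr), pr), collapse = ", "), "\n")
  invisible(x)
}

fit_weights <- function(scheme, weights) {
  # least-squares weights w_i (residuals scaled by sqrt(w_i))
  if (weights == "nex") sqrt(scheme$nex) else rep(1, length(scheme$b_values))
}

#' Coefficient of determination on the untransformed signal scale
#'
#' R^2 = 1 - SS_res / SS_tot computed on the measured (not log) signal.
#' Undefined (NA) for a zero-variance signal.
#'
#' @param values Measured signal per b-value.
#' @param fit A `model_fit` object or a numeric vector of fitted values.
#' @return R^2, <= 1, or NA when the signal has no variance.
#' @export
goodness_of_fit <- function(values, fit) {
  fitted <- if (inherits(fit, "model_fit")) fit$fitted else fit
  stopifnot(length(fitted) == length(values))
  ss_tot <- sum((values - mean(values))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((values - fitted)^2) / ss_tot
}

#' Fit the mono-exponential (Gaussian) model by log-linear least squares
#'
#' Ordinary least squares of log(signal) on b: the slope estimates -ADC and
#' the intercept log(S0). Voxels with any non-positive signal cannot be
#' log-transformed and are flagged unfittable rather than raising an error,
#' so volume fitting can skip them (they typically correspond to necrotic
#' or background voxels).
#'
#' @param values Measured signal per b-value of `scheme`.
#' @param scheme A [bvalue_scheme()].
#' @param weights `"none"` (default) for unweighted least squares or
#'   `"nex"` for weights proportional to sqrt(NEX).
#' @return A `model_fit` with `params$adc`, `params$s0`, `r_squared`,
#'   `converged` and a `status` string. A non-positive slope estimate is
#'   reported with `converged = FALSE` (the ADC invariant requires > 0).
#' @examples
#' sch <- default_bvalue_scheme()
#' fit <- fit_mono(signal_mono(sch$b_values, 1, 0.8e-3), sch)
#' fit$params$adc
#' @export
fit_mono <- function(values, scheme, weights = c("none", "nex")) {
  weights <- match.arg(weights)
  b <- scheme$b_values
  stopifnot(length(values) == length(b))
  na_fit <- list(s0 = NA_real_, adc = NA_real_)
  if (any(!is.finite(values)) || any(values <= 0))
    return(model_fit("mono", na_fit, values, rep(NA_real_, length(b)),
                     FALSE, "unfittable"))
  w <- fit_weights(scheme, weights)
  co <- stats::lm.wfit(cbind(1, b), log(values), w^2)$coefficients
  s0 <- exp(co[[1]]); adc <- -co[[2]]
  fitted <- exp(co[[1]] - b * adc)
  ok <- is.finite(adc) && adc > 0 && is.finite(s0) && s0 > 0
  model_fit("mono", list(s0 = s0, adc = adc), values, fitted,
            ok, if (ok) "ok" else "invalid_params")
}

nls_fit <- function(par0, lower, upper, resid_fn) {
  out <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                         ptol = 1e-10, gtol = 1e-10))
  list(par = out$par, converged = out$info %in% 1:4,
       status = if (out$info %in% 1:4) "ok" else paste0("nls_info_", out$info))
}

#' Fit the IVIM bi-exponential model
#'
#' Bounded non-linear least squares of the IVIM signal equation. In
#' `"segmented"` mode D and S0(1-f) are first estimated by a log-linear fit
#' to the high-b segment (b >= `b_threshold`, where the pseudo-diffusion
#' compartment has decayed away), then f and D* are estimated by bounded
#' non-linear least squares over all b with D held fixed. `"full"` mode
#' (default) refines all four parameters jointly starting from the
#' segmented solution. D* is parameterized as D + delta with delta >= 0,
#' so D* >= D always holds and the two compartments cannot swap.
#'
#' @inheritParams fit_mono
#' @param strategy `"full"` (segmented initialization + joint refinement)
#'   or `"segmented"` (D fixed at the high-b estimate).
#' @param b_threshold Segmentation threshold, s/mm^2; b-values at or above
#'   it form the perfusion-free segment. Default 200.
#' @param bounds See [default_fit_bounds()].
#' @param pseudo_exponent Passed to [signal_ivim()].
#' @return A `model_fit` with `params` `s0`, `d`, `d_star`, `f`. `status`
#'   is `"dstar_at_bound"` when delta is pinned at a box bound (a common
#'   symptom of an uninformative perfusion compartment).
#' @export
fit_ivim <- function(values, scheme, strategy = c("full", "segmented"),
                     b_threshold = 200, weights = c("none", "nex"),
                     bounds = default_fit_bounds(),
                     pseudo_exponent = "d_plus_dstar") {
  strategy <- match.arg(strategy)
  weights <- match.arg(weights)
  b <- scheme$b_values
  stopifnot(length(values) == length(b))
  high <- b >= b_threshold
  if (length(b) < 5 || sum(high) < 2 || sum(!high) < 2)
    stopf("need >= 5 b-values spanning the segmentation threshold")
  na_fit <- list(s0 = NA_real_, d = NA_real_, d_star = NA_real_, f = NA_real_)
  if (any(!is.finite(values)) || values[1] <= 0 || any(values[high] <= 0))
    return(model_fit("ivim", na_fit, values, rep(NA_real_, length(b)),
                     FALSE, "unfittable"))
  w <- fit_weights(scheme, weights)

  # stage 1: log-linear on the high-b segment -> D and S0*(1-f)
  co <- stats::lm.wfit(cbind(1, b[high]), log(values[high]),
                       w[high]^2)$coefficients
  d0 <- clamp(-co[[2]], bounds$d[1], bounds$d[2])
  s_perf_free <- exp(co[[1]])
  s0_0 <- max(values[1], s_perf_free)
  f0 <- clamp(1 - s_perf_free / s0_0, 0, 0.95)
  delta0 <- clamp(5e-3, bounds$d_star_delta[1] + 1e-6, bounds$d_star_delta[2])

  model_of <- function(s0, d, delta, f)
    signal_ivim(b, s0, d, d + delta, f, pseudo_exponent)

  # stage 2: f, D*, S0 with D fixed
  seg <- nls_fit(c(s0 = s0_0, delta = delta0, f = f0),
                 lower = c(1e-12, bounds$d_star_delta[1], bounds$f[1]),
                 upper = c(Inf, bounds$d_star_delta[2], bounds$f[2]),
                 function(p) w * (values - model_of(p[1], d0, p[2], p[3])))
  par <- c(s0 = unname(seg$par[1]), d = d0,
           delta = unname(seg$par[2]), f = unname(seg$par[3]))
  converged <- seg$converged
  status <- seg$status

  if (strategy == "full") {
    full <- nls_fit(par,
                    lower = c(1e-12, bounds$d[1], bounds$d_star_delta[1],
                              bounds$f[1]),
                    upper = c(Inf, bounds$d[2], bounds$d_star_delta[2],
                              bounds$f[2]),
                    function(p) w * (values - model_of(p[1], p[2], p[3], p[4])))
    par <- full$par
    converged <- full$converged
    status <- full$status
  }
  tol <- 1e-8
  if (status == "ok" &&
      (par[["delta"]] <= bounds$d_star_delta[1] + tol ||
       par[["delta"]] >= bounds$d_star_delta[2] - tol))
    status <- "dstar_at_bound"
  params <- list(s0 = par[["s0"]], d = par[["d"]],
                 d_star = par[["d"]] + par[["delta"]], f = par[["f"]])
  fitted <- model_of(par[["s0"]], par[["d"]], par[["delta"]], par[["f"]])
  model_fit("ivim", params, values, fitted, converged, status)
}

#' Fit the stretched-exponential model (SEM)
#'
#' Bounded non-linear least squares over (S0, DDC, alpha) with
#' alpha constrained to (0, 1]. Initialized from the mono-exponential fit
#' (DDC start = fitted ADC, alpha start 0.9); deterministic, no random
#' restarts, so volume fitting is reproducible.
#'
#' @inheritParams fit_ivim
#' @param alpha_start Starting value for the heterogeneity index.
#' @return A `model_fit` with `params` `s0`, `ddc`, `alpha`.
#' @export
fit_sem <- function(values, scheme, weights = c("none", "nex"),
                    bounds = default_fit_bounds(), alpha_start = 0.9) {
  weights <- match.arg(weights)
  b <- scheme$b_values
  stopifnot(length(values) == length(b))
  if (length(b) < 3) stopf("need >= 3 b-values")
  na_fit <- list(s0 = NA_real_, ddc = NA_real_, alpha = NA_real_)
  if (any(!is.finite(values)) || values[1] <= 0)
    return(model_fit("sem", na_fit, values, rep(NA_real_, length(b)),
                     FALSE, "unfittable"))
  w <- fit_weights(scheme, weights)
  mono <- fit_mono(values, scheme, weights)
  ddc0 <- if (mono$converged) clamp(mono$params$adc, bounds$ddc[1], bounds$ddc[2])
          else 1e-3
  s0_0 <- if (mono$converged) mono$params$s0 else values[1]
  out <- nls_fit(c(s0 = s0_0, ddc = ddc0, alpha = alpha_start),
                 lower = c(1e-12, bounds$ddc[1], bounds$alpha[1]),
                 upper = c(Inf, bounds$ddc[2], bounds$alpha[2]),
                 function(p) w * (values - signal_sem(b, p[1], p[2], p[3])))
  params <- list(s0 = out$par[["s0"]], ddc = out$par[["ddc"]],
                 alpha = out$par[["alpha"]])
  fitted <- signal_sem(b, params$s0, params$ddc, params$alpha)
  model_fit("sem", params, values, fitted, out$converged, out$status)
}

#' Fit all requested models voxelwise over a masked 4-D volume
#'
#' Applies [fit_mono()], [fit_ivim()] and/or [fit_sem()] to every
#' mask-positive voxel of a 4-D diffusion-weighted volume and returns one
#' 3-D parameter map per estimated quantity plus per-model R^2 maps and an
#' integer-coded fit-status map. Unfittable or non-converged voxels carry
#' NA in the affected maps. Deterministic given identical inputs.
#'
#' Status codes are additive flags: 0 all requested fits ok, +1 mono
#' failed, +2 IVIM failed, +4 SEM failed.
#'
#' @param dwi 4-D numeric array, dimensions (x, y, z, b).
#' @param mask 3-D array; voxels with `mask > 0` are fitted.
#' @param scheme A [bvalue_scheme()] matching the 4th dimension.
#' @param models Character subset of `c("mono", "ivim", "sem")`.
#' @param strategy,b_threshold Passed to [fit_ivim()].
#' @param weights Passed to every fitter.
#' @param bounds Passed to the non-linear fitters.
#' @return List with `maps` (named list of 3-D arrays: `adc`, `r2_mono`,
#'   `d`, `d_star`, `f`, `r2_ivim`, `ddc`, `alpha`, `r2_sem` as requested,
#'   plus `status`), `n_voxels` and `n_unfittable`.
#' @export
fit_volume <- function(dwi, mask, scheme,
                       models = c("mono", "ivim", "sem"),
                       strategy = "full", b_threshold = 200,
                       weights = "none", bounds = default_fit_bounds()) {
  models <- match.arg(models, several.ok = TRUE)
  dd <- dim(dwi)
  if (length(dd) != 4) stopf("dwi must be a 4-D array")
  if (!identical(dd[1:3], dim(mask)[1:3]))
    stopf("dwi and mask grids differ")
  if (dd[4] != length(scheme$b_values))
    stopf("4th dimension must match the number of b-values")
  map_names <- c(
    if ("mono" %in% models) c("adc", "r2_mono"),
    if ("ivim" %in% models) c("d", "d_star", "f", "r2_ivim"),
    if ("sem" %in% models) c("ddc", "alpha", "r2_sem"))
  maps <- c(lapply(map_names, function(.) array(NA_real_, dd[1:3])),
            list(array(NA_integer_, dd[1:3])))
  names(maps) <- c(map_names, "status")
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("mask is empty; returning empty maps")
    return(list(maps = maps, n_voxels = 0L, n_unfittable = 0L))
  }
  n_unfittable <- 0L
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    vals <- dwi[i, j, k, ]
    status <- 0L
    if ("mono" %in% models) {
      ft <- fit_mono(vals, scheme, weights)
      if (ft$converged) {
        maps$adc[i, j, k] <- ft$params$adc
        maps$r2_mono[i, j, k] <- ft$r_squared
      } else status <- status + 1L
    }
    if ("ivim" %in% models) {
      ft <- fit_ivim(vals, scheme, strategy, b_threshold, weights, bounds)
      if (ft$converged) {
        maps$d[i, j, k] <- ft$params$d
        maps$d_star[i, j, k] <- ft$params$d_star
        maps$f[i, j, k] <- ft$params$f
        maps$r2_ivim[i, j, k] <- ft$r_squared
      } else status <- status + 2L
    }
    if ("sem" %in% models) {
      ft <- fit_sem(vals, scheme, weights, bounds)
      if (ft$converged) {
        maps$ddc[i, j, k] <- ft$params$ddc
        maps$alpha[i, j, k] <- ft$params$alpha
        maps$r2_sem[i, j, k] <- ft$r_squared
      } else status <- status + 4L
    }
    maps$status[i, j, k] <- status
    if (status > 0L) n_unfittable <- n_unfittable + 1L
  }
  list(maps = maps, n_voxels = nrow(idx), n_unfittable = n_unfittable)
}
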