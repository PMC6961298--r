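#' Reference per-group parameter distributions
#'
#' Mean and standard deviation of every imaging parameter in the responder
#' and non-responder groups, on the reporting scale (diffusivities in
#' 10^-3 mm^2/s, f in percent, alpha unitless). These are the default
#' generating distributions of the cohort simulator: responders show lower
#' ADC, D and DDC and higher alpha than non-responders.
#'
#' @return Named list with elements `responder` and `non-responder`, each a
#'   named list of `c(mean, sd)` pairs for `adc`, `d`, `d_star`, `f`,
#'   `alpha`, `ddc`.
#' @export
reference_distributions <- function() {
  list(
    "responder" = list(
      adc    = c(mean = 0.610, sd = 0.072),
      d      = c(mean = 0.443, sd = 0.167),
      d_star = c(mean = 6.891, sd = 5.588),
      f      = c(mean = 25.318, sd = 9.069),
      alpha  = c(mean = 0.912, sd = 0.043),
      ddc    = c(mean = 0.831, sd = 0.141)),
    "non-responder" = list(
      adc    = c(mean = 0.980, sd = 0.089),
      d      = c(mean = 0.843, sd = 0.235),
      d_star = c(mean = 8.820, sd = 6.456),
      f      = c(mean = 32.356, sd = 10.723),
      alpha  = c(mean = 0.612, sd = 0.235),
      ddc    = c(mean = 1.257, sd = 0.167)))
}

# truncation bounds on the reporting scale, keeping draws inside the
# model-type invariants (and the fitter search box)
param_truncation_bounds <- function() {
  list(adc    = c(0.02, 4.99),
       d      = c(0.02, 4.99),
       ddc    = c(0.02, 4.99),
       d_star = c(0.2, 99),
       f      = c(0, 100),
       alpha  = c(0.01, 1))
}

# inverse-CDF truncated normal; sd = 0 degenerates to the mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  clamp(stats::qnorm(p, mean, sd), lower, upper)
}

#' Sample per-patient true parameters from a group distribution
#'
#' Truncated-normal draws of each imaging parameter, truncation at the
#' model-type invariant bounds (e.g. alpha <= 1, f in \[0, 100\]%). After
#' drawing, D* is floored at 1.05 D so the sampled IVIM parameters always
#' satisfy D* > D.
#'
#' @param n Number of patients.
#' @param dist One group's element of [reference_distributions()]
#'   (reporting scale).
#' @return Data frame (reporting scale) with columns `adc`, `d`, `d_star`,
#'   `f`, `alpha`, `ddc`.
#' @export
sample_patient_params <- function(n, dist) {
  tb <- param_truncation_bounds()
  out <- lapply(names(dist), function(p) {
    rtruncnorm(n, dist[[p]][["mean"]], dist[[p]][["sd"]],
               tb[[p]][1], tb[[p]][2])
  })
  names(out) <- names(dist)
  out <- as.data.frame(out)
  out$d_star <- pmax(out$d_star, out$d * 1.05)
  out
}

#' Add Rician noise to a magnitude signal
#'
#' Magnitude MR images carry Rician noise: the observed value is
#' sqrt((S + e1)^2 + e2^2) with e1, e2 ~ N(0, sigma^2). At low SNR this
#' positively biases the measured signal (the Rician floor).
#'
#' @param s Noiseless signal values.
#' @param sigma Noise standard deviation (may be a vector matching `s`;
#'   sigma = 0 returns `s` unchanged, consuming no random numbers).
#' @return Noisy magnitude values.
#' @export
rician_noise <- function(s, sigma) {
  if (all(sigma == 0)) return(s)
  sqrt((s + stats::rnorm(length(s), 0, sigma))^2 +
       stats::rnorm(length(s), 0, sigma)^2)
}

# per-b noise sd: NEX averaging reduces noise by sqrt(NEX), referenced to
# the b = 0 acquisition
noise_sigma <- function(scheme, snr_b0, s0) {
  if (is.infinite(snr_b0)) return(rep(0, length(scheme$b_values)))
  s0 / (snr_b0 * sqrt(scheme$nex / scheme$nex[1]))
}

#' Simulate voxel signals for one patient
#'
#' Generates `n_voxels` signal decays from the designated forward model
#' using the patient's true parameters, with small multiplicative
#' between-voxel jitter (truncated at the parameter invariants) standing
#' in for within-tumor heterogeneity, then corrupts them with Rician noise
#' scaled per b-value by the NEX averaging of the scheme:
#' sigma_b = s0 / (snr_b0 sqrt(NEX_b / NEX_b0)). `snr_b0 = Inf` yields the
#' exact noiseless forward signals.
#'
#' @param params One-row data frame (or named vector) of true parameters
#'   on the reporting scale, as from [sample_patient_params()]. Only the
#'   parameters of `model` are used.
#' @param scheme A [bvalue_scheme()].
#' @param snr_b0 Signal-to-noise ratio at b = 0 (Inf = noiseless).
#' @param model Generating model: `"sem"` (default), `"ivim"` or `"mono"`.
#' @param n_voxels Number of voxels to simulate.
#' @param s0 b = 0 signal scale (arbitrary units).
#' @param voxel_cv Coefficient of variation of the within-tumor parameter
#'   jitter (default 0.05).
#' @return List with `signals` (matrix n_voxels x n_b) and `true_voxel`
#'   (data frame of per-voxel true parameters, reporting scale).
#' @export
generate_voxel_signals <- function(params, scheme, snr_b0,
                                   model = c("sem", "ivim", "mono"),
                                   n_voxels = 1, s0 = 100, voxel_cv = 0.05) {
  model <- match.arg(model)
  stopifnot(snr_b0 > 0)
  p <- as.list(as.data.frame(params))
  tb <- param_truncation_bounds()
  need <- switch(model, mono = "adc", ivim = c("d", "d_star", "f"),
                 sem = c("ddc", "alpha"))
  vox <- lapply(need, function(nm) {
    jitter <- if (voxel_cv > 0) 1 + stats::rnorm(n_voxels, 0, voxel_cv) else
      rep(1, n_voxels)
    clamp(p[[nm]][1] * jitter, tb[[nm]][1], tb[[nm]][2])
  })
  names(vox) <- need
  vox <- as.data.frame(vox)
  if (model == "ivim") vox$d_star <- pmax(vox$d_star, vox$d * 1.05)
  b <- scheme$b_values
  sig <- matrix(NA_real_, n_voxels, length(b))
  for (v in seq_len(n_voxels)) {
    pv <- to_internal_units(unlist(vox[v, , drop = FALSE]))
    sig[v, ] <- switch(model,
      mono = signal_mono(b, s0, pv[["adc"]]),
      ivim = signal_ivim(b, s0, pv[["d"]], pv[["d_star"]], pv[["f"]]),
      sem  = signal_sem(b, s0, pv[["ddc"]], pv[["alpha"]]))
  }
  sigma <- noise_sigma(scheme, snr_b0, s0)
  noisy <- t(apply(sig, 1, rician_noise, sigma = sigma))
  list(signals = noisy, true_voxel = vox)
}

#' Simulation configuration
#'
#' Conditions under which a synthetic cohort is generated. Defaults match
#' the reference study: 58 responders and 26 non-responders imaged with
#' the 12-b-value scheme. Each patient's phantom is a small multi-slice
#' grid whose tumor mask spans `n_slices` slices with unequal per-slice
#' areas (so the area-weighted VOI rule is actually exercised).
#'
#' @param n_responders,n_nonresponders Group sizes (>= 1).
#' @param scheme A [bvalue_scheme()].
#' @param snr_b0 SNR at b = 0 (default 100; Inf = noiseless).
#' @param voxels_per_patient Total tumor voxels per patient (default 48).
#' @param grid_dim Phantom grid (x, y, slices), default c(8, 8, 3).
#' @param s0 b = 0 signal scale.
#' @param voxel_cv Within-tumor parameter CV (default 0.05).
#' @param seed Mandatory integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_responders = 58, n_nonresponders = 26,
                       scheme = default_bvalue_scheme(), snr_b0 = 100,
                       voxels_per_patient = 48, grid_dim = c(8, 8, 3),
                       s0 = 100, voxel_cv = 0.05, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stopf("an integer seed is mandatory")
  if (n_responders < 1 || n_nonresponders < 1)
    stopf("group sizes must be >= 1")
  if (voxels_per_patient < 1) stopf("voxels_per_patient must be >= 1")
  if (voxels_per_patient > prod(grid_dim))
    stopf("voxels_per_patient exceeds the phantom grid")
  structure(list(n_responders = as.integer(n_responders),
                 n_nonresponders = as.integer(n_nonresponders),
                 scheme = scheme, snr_b0 = snr_b0,
                 voxels_per_patient = as.integer(voxels_per_patient),
                 grid_dim = as.integer(grid_dim), s0 = s0,
                 voxel_cv = voxel_cv, seed = as.integer(seed)),
            class = "sim_config")
}

# split the tumor voxels over slices roughly 1:2:1 (middle slice largest),
# so slice areas differ and the VOI weighting is non-trivial
tumor_mask <- function(grid_dim, n_voxels) {
  n_slices <- grid_dim[3]
  w <- stats::dnorm(seq_len(n_slices), mean = (n_slices + 1) / 2,
                    sd = max(n_slices / 4, 0.5))
  counts <- floor(w / sum(w) * n_voxels)
  rem <- n_voxels - sum(counts)
  if (rem > 0) {
    ord <- order(w, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  mask <- array(0L, grid_dim)
  for (k in seq_len(n_slices)) {
    if (counts[k] > 0) mask[, , k][seq_len(counts[k])] <- 1L
  }
  mask
}

#' Generate a synthetic patient cohort with phantom volumes
#'
#' Builds the full synthetic study for one generating model: per patient,
#' true imaging parameters drawn from the group's distribution, a
#' multi-slice tumor phantom of noisy voxel signals, a response category,
#' and categorical clinical covariates drawn from the reference cohort's
#' printed proportions. Every output is a pure function of
#' (`config`, `dists`, `model`).
#'
#' @param config A [sim_config()].
#' @param dists Per-group distributions, see [reference_distributions()].
#' @param model Generating forward model (`"sem"` default).
#' @param category_probs Per-group response-category probabilities used to
#'   assign CR/PR (responders) and SD/PD (non-responders).
#' @return List with `patients` (per patient: `patient_id`, `group`,
#'   `category`, `true` parameters, `volume` 4-D array, `mask`),
#'   `truth` (data frame of true parameters, reporting scale),
#'   `covariates`, `config`, `model`.
#' @export
generate_cohort <- function(config, dists = reference_distributions(),
                            model = c("sem", "ivim", "mono"),
                            category_probs = list(
                              "responder" = c(CR = 0.35, PR = 0.65),
                              "non-responder" = c(SD = 0.8, PD = 0.2))) {
  model <- match.arg(model)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_responders + config$n_nonresponders
  groups <- rep(c("responder", "non-responder"),
                c(config$n_responders, config$n_nonresponders))
  truth <- rbind(sample_patient_params(config$n_responders,
                                       dists[["responder"]]),
                 sample_patient_params(config$n_nonresponders,
                                       dists[["non-responder"]]))
  truth <- cbind(patient_id = sprintf("P%03d", seq_len(n)),
                 group = groups, truth)
  category <- vapply(seq_len(n), function(i) {
    pr <- category_probs[[groups[i]]]
    sample(names(pr), 1, prob = pr)
  }, character(1))
  covariates <- generate_covariates(groups)
  mask <- tumor_mask(config$grid_dim, config$voxels_per_patient)
  vox_idx <- which(mask > 0, arr.ind = TRUE)
  nb <- length(config$scheme$b_values)
  patients <- lapply(seq_len(n), function(i) {
    gen <- generate_voxel_signals(truth[i, c("adc", "d", "d_star", "f",
                                             "alpha", "ddc")],
                                  config$scheme, config$snr_b0, model,
                                  n_voxels = nrow(vox_idx), s0 = config$s0,
                                  voxel_cv = config$voxel_cv)
    vol <- array(0, c(config$grid_dim, nb))
    for (v in seq_len(nrow(vox_idx)))
      vol[vox_idx[v, 1], vox_idx[v, 2], vox_idx[v, 3], ] <- gen$signals[v, ]
    list(patient_id = truth$patient_id[i], group = groups[i],
         category = category[i], true = truth[i, ], volume = vol,
         mask = mask)
  })
  list(patients = patients, truth = truth,
       covariates = cbind(patient_id = truth$patient_id, group = groups,
                          category = category, covariates),
       config = config, model = model)
}

# categorical covariates drawn from the reference cohort's printed
# per-group proportions (responders n=58 / non-responders n=26)
generate_covariates <- function(groups) {
  props <- list(
    tumor_size_class = list("responder" = c("<=4cm" = 0.750, ">4cm" = 0.250),
                            "non-responder" = c("<=4cm" = 0.231, ">4cm" = 0.769)),
    figo_stage = list("responder" = c(IIB = 0.138, III = 0.448, IV = 0.414),
                      "non-responder" = c(IIB = 0.231, III = 0.385, IV = 0.385)),
    pathologic_type = list("responder" = c(squamous = 0.828, other = 0.172),
                           "non-responder" = c(squamous = 0.808, other = 0.192)),
    histologic_grade = list(
      "responder" = c("well/moderate" = 0.310, poor = 0.690),
      "non-responder" = c("well/moderate" = 0.769, poor = 0.231)))
  age_rng <- list("responder" = c(40, 25, 67), "non-responder" = c(38, 29, 68))
  out <- data.frame(age = vapply(groups, function(g) {
    round(rtruncnorm(1, age_rng[[g]][1], 10, age_rng[[g]][2], age_rng[[g]][3]))
  }, numeric(1)))
  for (cv in names(props)) {
    out[[cv]] <- vapply(groups, function(g) {
      p <- props[[cv]][[g]]
      sample(names(p), 1, prob = p)
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

#' Trajectory-generator configuration
#'
#' Visit grid and per-category diameter-change distributions for the
#' longitudinal tumor-diameter simulator. The first follow-up falls at
#' 1.5 months (4-6 weeks after the start of treatment) and subsequent
#' visits every 3 months up to 18 months. Change fractions are relative
#' to baseline at the 12-month assessment: PR draws a shrinkage strictly
#' beyond 30%, SD a change inside the (-30%, +20%) band (with a safety
#' margin so measurement rounding cannot cross a boundary), PD a growth
#' of at least 20%; CR reaches diameter 0 at a visit within 12 months.
#'
#' @param visit_months Follow-up visit grid (months).
#' @param pr_shrink,sd_change,pd_growth Length-2 ranges of the uniform
#'   change-fraction draws per category.
#' @param cr_months Candidate visits at which a CR lesion disappears.
#' @param baseline_mm Range of baseline diameters (mm).
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(visit_months = c(1.5, 3, 6, 9, 12, 15, 18),
                              pr_shrink = c(0.35, 0.75),
                              sd_change = c(-0.25, 0.15),
                              pd_growth = c(0.22, 0.50),
                              cr_months = c(3, 6, 9, 12),
                              baseline_mm = c(20, 60)) {
  structure(list(visit_months = visit_months, pr_shrink = pr_shrink,
                 sd_change = sd_change, pd_growth = pd_growth,
                 cr_months = cr_months, baseline_mm = baseline_mm),
            class = "trajectory_config")
}

#' Simulate longitudinal diameter trajectories for labeled patients
#'
#' For each patient, draws a baseline diameter and a trajectory over the
#' visit grid whose 12-month assessment reproduces the intended response
#' category by construction (closure: [classify_response()] applied to
#' the output returns the intended label for every patient).
#'
#' @param labels Data frame with columns `patient_id` and `category`
#'   (CR/PR/SD/PD).
#' @param tconfig A [trajectory_config()].
#' @param seed Optional integer seed.
#' @return List with `baselines` (patient_id, baseline_mm) and `visits`
#'   (patient_id, months, diameter_mm, long format).
#' @export
generate_trajectories <- function(labels, tconfig = trajectory_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vm <- tconfig$visit_months
  one <- function(pid, category) {
    base <- stats::runif(1, tconfig$baseline_mm[1], tconfig$baseline_mm[2])
    if (category == "CR") {
      cr_at <- sample(tconfig$cr_months, 1)
      frac <- pmax(0, 1 - vm / cr_at)  # linear shrink to 0 at cr_at, 0 after
      d <- base * frac
    } else {
      change12 <- switch(category,
        PR = -stats::runif(1, tconfig$pr_shrink[1], tconfig$pr_shrink[2]),
        SD = stats::runif(1, tconfig$sd_change[1], tconfig$sd_change[2]),
        PD = stats::runif(1, tconfig$pd_growth[1], tconfig$pd_growth[2]))
      # smooth path reaching the drawn change exactly at 12 months,
      # flat afterwards; always > 0 so no accidental CR
      frac <- 1 + change12 * pmin(vm, 12) / 12
      d <- pmax(base * frac, 1)
    }
    list(baseline = data.frame(patient_id = pid, baseline_mm = base),
         visits = data.frame(patient_id = pid, months = vm, diameter_mm = d))
  }
  out <- Map(one, labels$patient_id, labels$category)
  list(baselines = do.call(rbind, c(lapply(out, `[[`, "baseline"),
                                    list(make.row.names = FALSE))),
       visits = do.call(rbind, c(lapply(out, `[[`, "visits"),
                                 list(make.row.names = FALSE))))
}

#' Simulate two readers' measurements of the same values
#'
#' Two independent Gaussian-noise copies of a vector of true per-patient
#' VOI values, emulating the measurement variability of two blinded
#' readers. Feeding both copies to [lin_ccc()] yields a concordance that
#' approaches 1 as `reader_sd` goes to 0.
#'
#' @param values True values.
#' @param reader_sd Standard deviation of each reader's measurement error
#'   (>= 0), same units as `values`.
#' @param seed Optional integer seed.
#' @return List with `reader1` and `reader2`.
#' @export
simulate_readers <- function(values, reader_sd, seed = NULL) {
  stopifnot(reader_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  list(reader1 = values + stats::rnorm(n, 0, reader_sd),
       reader2 = values + stats::rnorm(n, 0, reader_sd))
}
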