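#' Per-patient VOI parameter values from a phantom cohort
#'
#' Runs the voxelwise fitters over every patient's volume and reduces each
#' parameter map to the patient's VOI value by the area-weighted rule.
#' Values are returned on the reporting scale (diffusivities in
#' 10^-3 mm^2/s, f in percent).
#'
#' @param cohort A cohort from [generate_cohort()] (or any list of
#'   patients with `volume`, `mask`, `patient_id`, `group`).
#' @param models Which models to fit (default: the cohort's generating
#'   model only).
#' @param pixdim In-plane voxel dimensions for the ROI areas.
#' @return Data frame with `patient_id`, `group`, `n_slices` and one
#'   column per fitted parameter (`adc`, `d`, `d_star`, `f`, `ddc`,
#'   `alpha` as requested).
#' @export
fit_cohort_voi <- function(cohort, models = cohort$model, pixdim = c(1, 1)) {
  param_cols <- c(if ("mono" %in% models) "adc",
                  if ("ivim" %in% models) c("d", "d_star", "f"),
                  if ("sem" %in% models) c("ddc", "alpha"))
  rows <- lapply(cohort$patients, function(pt) {
    fv <- fit_volume(pt$volume, pt$mask, cohort$config$scheme, models)
    vals <- vapply(param_cols, function(p) {
      voi_from_map(fv$maps[[p]], pt$mask, pixdim)$value
    }, numeric(1))
    n_slices <- voi_from_map(fv$maps[[param_cols[1]]], pt$mask,
                             pixdim)$n_slices
    df <- data.frame(patient_id = pt$patient_id, group = pt$group,
                     n_slices = n_slices)
    df[param_cols] <- as.list(to_reporting_units(vals))
    df
  })
  do.call(rbind, rows)
}

#' Run the full simulated study
#'
#' End-to-end pipeline: simulate the cohort, fit every model voxelwise,
#' aggregate to per-patient VOI values, simulate longitudinal diameter
#' trajectories and classify response, then compute the group-comparison,
#' ROC and reader-agreement statistics.
#'
#' One phantom cohort is generated per model family (mono, IVIM, SEM),
#' sharing the group structure: each family's parameters are estimated
#' from signals generated by its own forward model, so the per-patient
#' estimates are commensurate with the generating distributions.
#'
#' @param seed Integer seed driving every random draw.
#' @param config Optional [sim_config()] (its `seed` is overridden by
#'   `seed`).
#' @param dists Generating distributions, see [reference_distributions()].
#' @param tconfig A [trajectory_config()].
#' @param reader_cv Reader measurement error as a fraction of each
#'   parameter's cohort mean (used for the CCC table).
#' @return List with `analysis_table` (per-patient fitted parameters +
#'   covariates + classified labels), `truth` (per-family true
#'   parameters), `group_stats` (Table-2-style comparison),
#'   `roc_table` (Table-3-style ROC rows), `auc_comparisons` (paired
#'   DeLong tests of DDC against the other markers), `agreement`
#'   (per-parameter CCC), `labels`, `trajectories` and `config`.
#' @export
run_study <- function(seed, config = NULL, dists = reference_distributions(),
                      tconfig = trajectory_config(), reader_cv = 0.05) {
  cfg <- config %||% sim_config(seed = seed)
  cfg$seed <- as.integer(seed)
  families <- list(mono = "adc", ivim = c("d", "d_star", "f"),
                   sem = c("ddc", "alpha"))
  cohorts <- list()
  fitted <- NULL
  truth <- list()
  for (fam in names(families)) {
    cfg_f <- cfg
    # distinct stream per family so the three phantom scans are independent
    cfg_f$seed <- cfg$seed + match(fam, names(families)) - 1L
    cohorts[[fam]] <- generate_cohort(cfg_f, dists, model = fam)
    voi <- fit_cohort_voi(cohorts[[fam]])
    truth[[fam]] <- cohorts[[fam]]$truth[c("patient_id", "group",
                                           families[[fam]])]
    keep <- voi[c("patient_id", "group", families[[fam]])]
    fitted <- if (is.null(fitted)) keep else
      merge(fitted, keep[c("patient_id", families[[fam]])],
            by = "patient_id", sort = FALSE)
  }
  covariates <- cohorts$sem$covariates

  traj <- generate_trajectories(
    covariates[c("patient_id", "category")], tconfig,
    seed = cfg$seed + 100L)
  labels <- classify_cohort(traj$baselines, traj$visits)
  analysis_table <- merge(fitted, covariates[setdiff(names(covariates),
                                                     "group")],
                          by = "patient_id", sort = FALSE)
  analysis_table <- merge(analysis_table,
                          labels[c("patient_id", "category",
                                   "decided_at_months")],
                          by = "patient_id", sort = FALSE,
                          suffixes = c("_intended", ""))

  params <- c("adc", "d", "d_star", "f", "alpha", "ddc")
  group_stats <- group_comparison_table(analysis_table, params)
  roc_params <- c(adc = "lower", d = "lower", alpha = "higher",
                  ddc = "lower")
  roc_table <- roc_parameter_table(analysis_table, roc_params)
  auc_comparisons <- do.call(rbind, lapply(c("adc", "d", "alpha"), function(p) {
    cmp <- compare_auc(analysis_table$ddc, analysis_table[[p]],
                       analysis_table$group,
                       direction_a = "lower",
                       direction_b = unname(roc_params[p]))
    data.frame(comparison = paste0("ddc_vs_", p), auc_ddc = cmp$auc_a,
               auc_other = cmp$auc_b, p = cmp$p)
  }))
  agreement <- do.call(rbind, lapply(params, function(p) {
    vals <- analysis_table[[p]]
    rd <- simulate_readers(vals, reader_cv * mean(vals),
                           seed = cfg$seed + 200L + match(p, params))
    cc <- lin_ccc(rd$reader1, rd$reader2)
    data.frame(parameter = p, ccc = cc$ccc, band = cc$band)
  }))
  list(analysis_table = analysis_table, truth = truth,
       group_stats = group_stats, roc_table = roc_table,
       auc_comparisons = auc_comparisons, agreement = agreement,
       labels = labels, trajectories = traj, config = cfg)
}

#' Group-comparison table of imaging parameters
#'
#' Mean +/- SD per responder group and the unpaired two-tailed
#' pooled-variance t test, one row per parameter (the layout of a
#' responders-vs-non-responders comparison table).
#'
#' @param tab Data frame with a `group` column and one column per
#'   parameter (reporting scale).
#' @param params Parameter column names.
#' @return Data frame with `parameter`, `mean_responder`, `sd_responder`,
#'   `mean_nonresponder`, `sd_nonresponder`, `t`, `p`.
#' @export
group_comparison_table <- function(tab, params) {
  r <- tab$group == "responder"
  do.call(rbind, lapply(params, function(p) {
    tt <- two_group_t(tab[[p]][r], tab[[p]][!r])
    data.frame(parameter = p,
               mean_responder = mean(tab[[p]][r]),
               sd_responder = stats::sd(tab[[p]][r]),
               mean_nonresponder = mean(tab[[p]][!r]),
               sd_nonresponder = stats::sd(tab[[p]][!r]),
               t = tt$t, p = tt$p)
  }))
}

#' ROC table of imaging parameters
#'
#' One [roc_analysis()] row per parameter: cutoff, AUC with 95% CI,
#' sensitivity and specificity at the Youden-optimal cutoff.
#'
#' @param tab Data frame with `group` and parameter columns.
#' @param directions Named character vector mapping parameter name to
#'   orientation (`"lower"`/`"higher"`/`"auto"`).
#' @return Data frame, one row per parameter.
#' @export
roc_parameter_table <- function(tab, directions) {
  do.call(rbind, lapply(names(directions), function(p) {
    r <- roc_analysis(tab[[p]], tab$group,
                      direction = unname(directions[p]))
    data.frame(parameter = p, cutoff = r$cutoff, auc = r$auc,
               ci_low = r$ci95[1], ci_high = r$ci95[2],
               sensitivity = r$sensitivity, specificity = r$specificity,
               orientation = r$orientation)
  }))
}
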