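#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study cohort.
#
# Builds one phantom cohort per model family (mono / IVIM / SEM) with the
# default group structure (58 responders, 26 non-responders), SNR 100 at
# b = 0 and the 12-b-value protocol, plus longitudinal tumor-diameter
# trajectories for every patient. Volumes and masks go to scratch/ as
# NIfTI; tables go to results/ as CSV.

suppressPackageStartupMessages(library(dwiresponse))

seed <- 1234L
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

for (fam in c("mono", "ivim", "sem")) {
  cfg <- sim_config(seed = seed + match(fam, c("mono", "ivim", "sem")) - 1L)
  co <- generate_cohort(cfg, model = fam)
  write_cohort(co, file.path("scratch/sim", fam))
  cat(sprintf("wrote %s cohort: %d patients (%d responders), SNR %g\n",
              fam, length(co$patients), cfg$n_responders, cfg$snr_b0))
  if (fam == "sem") {
    utils::write.csv(co$covariates, "results/sim/covariates.csv",
                     row.names = FALSE)
    traj <- generate_trajectories(co$covariates[c("patient_id", "category")],
                                  seed = seed + 100L)
    utils::write.csv(traj$baselines, "results/sim/baselines.csv",
                     row.names = FALSE)
    utils::write.csv(traj$visits, "results/sim/visits.csv",
                     row.names = FALSE)
    cat(sprintf("wrote trajectories: %d visits for %d patients\n",
                nrow(traj$visits), nrow(traj$baselines)))
  }
}
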