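# dwiresponse

Multi-model diffusion-weighted MRI (DWI) analysis for predicting tumor
response to radiochemotherapy.

Quantitative DWI measures how the MR signal decays with diffusion
weighting `b`. Which mathematical decay model best converts that decay
into a predictive imaging biomarker is an open question in oncologic
imaging; this package implements the complete comparison pipeline for
the three standard candidates on multi-b-value acquisitions:

* **mono-exponential (Gaussian)** — `S(b)/S0 = exp(−b·ADC)`
* **IVIM (bi-exponential)** —
  `S(b)/S0 = (1−f)·exp(−b·D) + f·exp(−b·(D+D*))`, separating slow tissue
  diffusion `D` from capillary pseudo-diffusion (`D*`, perfusion
  fraction `f`)
* **stretched-exponential (SEM)** — `S(b)/S0 = exp(−(b·DDC)^α)`, with
  distributed diffusion coefficient `DDC` and heterogeneity index
  `α ∈ (0, 1]`

Around the fitters the package provides the rest of the analysis chain a
response-prediction study needs: voxelwise map fitting over NIfTI
volumes, area-weighted volume-of-interest (VOI) aggregation
(`ΣAV / ΣA`), size-based CR/PR/SD/PD response classification from
longitudinal diameter series, and the biomarker statistics layer —
Lin's concordance correlation coefficient for two-reader agreement,
pooled-variance t tests, chi-square/Fisher covariate tests, empirical
ROC with Youden-optimal cutoffs, and paired DeLong AUC comparison. A
synthetic phantom/cohort generator (truncated-normal group parameter
distributions, Rician noise with √NEX averaging, response-consistent
diameter trajectories) makes the whole chain testable end to end.

Intended users: imaging scientists building or validating quantitative
DWI biomarker pipelines, and anyone needing a tested reference
implementation of IVIM/SEM fitting plus the associated ROC/agreement
statistics.

## Worked example

Fit the stretched-exponential model to a noiseless decay over the
default 12-b-value protocol (b = 0…1500 s/mm²):

```r
library(dwiresponse)
sch <- default_bvalue_scheme()
sig <- signal_sem(sch$b_values, s0 = 1, ddc = 0.972e-3, alpha = 0.910)
fit_sem(sig, sch)
#> <sem fit>  converged: TRUE  status: ok  R^2: 1.0000
#>   s0 = 1, ddc = 0.000972, alpha = 0.91
```

The fitter returns exactly the generating parameters: `ddc` in mm²/s
(0.972 ×10⁻³ mm²/s on the conventional reporting scale) and the
heterogeneity index `α = 0.91`; `R² = 1` because the input is noiseless.
Two-reader agreement works the same way:

```r
r <- lin_ccc(c(1.01, 0.83, 1.24, 0.97, 1.15), c(0.98, 0.86, 1.19, 1.02, 1.12))
#> CCC = 0.954 (good)
```

## The analysis workflow

The `analysis/` scripts run the full simulated study (84 patients:
58 responders / 26 non-responders, SNR 100, one phantom cohort per model
family) and write their tables under `results/` (volumes and parameter
maps under `scratch/`):

```sh
Rscript analysis/01_simulate.R   # phantom cohorts + diameter trajectories
Rscript analysis/02_fit.R        # voxelwise fits -> VOI parameter table
Rscript analysis/03_classify.R   # CR/PR/SD/PD + responder groups
Rscript analysis/04_stats.R      # group comparison, ROC, DeLong, CCC
```

On the default seed the pipeline recovers the generating group means to
within ~1%, classifies every simulated trajectory back to its intended
category, finds responders lower in ADC/D/DDC and higher in α (all
t-test p < 0.05), and yields AUCs in the 0.93–0.99 range with the
Youden cutoff, sensitivity and specificity reported per parameter.

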