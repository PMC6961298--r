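---
title: "Comparing diffusion decay models for treatment-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing diffusion decay models for treatment-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiresponse)
```

## The problem

Multi-b-value diffusion-weighted MRI (DWI) probes tissue microstructure by
measuring how the MR signal attenuates with increasing diffusion weighting
b (s/mm²). In tumors treated with radiochemotherapy, pre-treatment
diffusion parameters carry predictive information: densely cellular,
well-oxygenated tumors (low diffusivity) tend to respond, while necrotic,
heterogeneous tumors (high diffusivity, low homogeneity) tend to resist.
This package implements the full analysis chain needed to compare three
decay models as response predictors on one cohort: forward models, voxel
fitting, volume-of-interest (VOI) aggregation, response classification,
and the biomarker statistics layer — plus a synthetic phantom/cohort
generator so every stage is testable without patient data.

## The three decay models

With $S_0$ the signal at $b = 0$:

* **Mono-exponential (Gaussian)**: $S(b)/S_0 = e^{-b\,\mathrm{ADC}}$.
  Free Brownian diffusion; a single apparent diffusion coefficient.
* **IVIM (bi-exponential)**:
  $S(b)/S_0 = (1-f)\,e^{-bD} + f\,e^{-b(D + D^*)}$.
  Separates slow (true) diffusion $D$ from perfusion-driven
  pseudo-diffusion ($D^*$, volume fraction $f$) in the capillary network.
  The pseudo-compartment decay rate is implemented exactly as written,
  $D + D^*$; some implementations use $D^*$ alone, and
  `signal_ivim(..., pseudo_exponent = "dstar")` exposes that variant
  because which convention a given vendor uses is generally not
  documented.
* **Stretched-exponential (SEM)**:
  $S(b)/S_0 = e^{-(b\,\mathrm{DDC})^\alpha}$.
  The distributed diffusion coefficient DDC is a mean intravoxel
  diffusion rate; $\alpha \in (0, 1]$ indexes intravoxel heterogeneity
  ($\alpha = 1$ recovers the Gaussian model; smaller $\alpha$ = more
  heterogeneous diffusion environments).

All models are carried internally in mm²/s (and $f$ as a proportion);
the conventional reporting scale (diffusivities ×10⁻³ mm²/s, $f$ in %)
is applied only at the table/report boundary, which avoids silent
thousand-fold unit errors. Note that the decimal rescaling by 1000 is not
bit-exact in binary floating point; round-tripping parameters through the
reporting scale perturbs them by at most one unit in the last place, and
the property tests assert the round-trip at that tolerance.

## Acquisition scheme

The default protocol (`default_bvalue_scheme()`) uses 12 b-values —
0, 10, 25, 50, 75, 100, 150, 200, 400, 800, 1000, 1500 s/mm² — with
per-b excitation counts (NEX) 1, 3, 3, 3, 3, 2, 2, 2, 2, 3, 5, 6. The
dense low-b sampling resolves the fast pseudo-diffusion decay; the
high-b points pin down the slow tail where averaging more excitations
compensates the lower signal.

## Fitting

* **Mono**: ordinary least squares of $\log S$ on $b$ (`fit_mono()`),
  the classical log-linear ADC estimator. Voxels with any non-positive
  signal cannot be log-transformed; they are flagged unfittable and
  excluded (and counted), the numerical analogue of excluding necrotic or
  cystic regions from a manual ROI. All 12 b-values enter the ADC by
  default; a subset can be selected by constructing a reduced scheme.
* **IVIM**: bounded non-linear least squares (`fit_ivim()`,
  Levenberg–Marquardt via minpack.lm). The segmented stage first
  estimates $D$ and $S_0(1-f)$ by a log-linear fit to $b \ge$ 200 s/mm²
  — the largest "low" b in the scheme before the jump to 400, the
  standard choice for the perfusion-free segment — then fits $f$, $D^*$,
  $S_0$ with $D$ fixed; `strategy = "full"` (the default) refines all
  four parameters jointly from that start. $D^*$ is parameterized as
  $D + \delta$ with $\delta \in [0, 0.1]$ mm²/s so $D^* \ge D$ holds by
  construction and the two exponentials cannot swap labels; a $\delta$
  pinned at a bound is flagged (`dstar_at_bound`), the classic symptom of
  an uninformative perfusion compartment.
* **SEM**: bounded non-linear least squares over $(S_0, \mathrm{DDC},
  \alpha)$, initialized from the mono fit with $\alpha$ starting at 0.9.

Numerical choices: box bounds ADC, $D$, DDC $\in [10^{-5}, 5\times
10^{-3}]$ mm²/s, $f \in [0,1]$, $\alpha \in [0.01, 1]$ (physiologic
ranges many standard deviations wide); convergence tolerances $10^{-10}$
with at most 500 iterations; unweighted least squares by default
(`weights = "nex"` optionally weights residuals by $\sqrt{\mathrm{NEX}}$);
initialization is deterministic — no random restarts — so `fit_volume()`
is reproducible bit-for-bit. Goodness of fit is $R^2 = 1 -
SS_{res}/SS_{tot}$ on the untransformed signal scale; for a zero-variance
signal it is undefined and reported missing. Because the SEM family nests
the mono model ($\alpha = 1$), a converged SEM fit can never have lower
$R^2$ than the mono fit of the same voxel — vendor reports where the
richer model scores *worse* than its nested special case on the same
curve indicate fitting instability, not model failure, and such orderings
are deliberately not reproduced here.

## VOI aggregation and response classification

Per-slice ROI means are combined into the patient-level VOI value by the
area-weighted rule $\sum_i A_i V_i / \sum_i A_i$ (`voi_weighted_mean()`).
The result is invariant to uniform rescaling of the areas, so physical
mm² and raw voxel counts give identical values; missing (unfittable)
voxels contribute to neither $A$ nor $V$.

Response is classified from longitudinal largest-axial-diameter series
(`classify_response()`): complete response (CR) at the first visit within
12 months where the lesion has disappeared (diameter ≤ a configurable
epsilon, default 0 mm — simulated series are noise-free at zero);
otherwise, at the visit nearest 12 months (quarterly visit grid; ties
broken toward the earlier visit), partial response (PR) for a decrease of
*strictly more than* 30%, progressive disease (PD) for an increase of
*at least* 20%, stable disease (SD) between. CR/PR form the responder
group, SD/PD the non-responders. Patients with no assessable visit at or
before 12 months are flagged excluded rather than classified — interim
progression before the 12-month assessment is treated as exclusion, not
immediate PD, matching the upstream-exclusion reading of the rules.

## Statistics layer

* **Agreement**: Lin's concordance correlation coefficient with
  population (1/n) moments; bands good (> 0.75), moderate (0.40–0.75)
  and poor (< 0.40). The boundary 0.40 itself is assigned to "moderate"
  (the conventional band phrasing leaves it unassigned).
* **Group comparison**: unpaired two-tailed Student's t with pooled
  variance (the era's SPSS default; Welch behind `var_equal = FALSE`);
  chi-square without continuity correction for categorical covariates,
  falling back to Fisher's exact test when any expected count is below 5.
* **ROC**: empirical ROC with trapezoidal AUC — computed as the
  Mann–Whitney U-statistic via midranks, so it is exact under ties and
  scales to very large simulated cohorts. The cutoff maximizes Youden's
  $J$ over thresholds midway between adjacent observed values; ties in
  $J$ break toward higher sensitivity, then the lower threshold. CIs use
  the DeLong variance with a normal approximation.
* **AUC comparison**: paired DeLong z-test from the structural
  components (a documented choice — the method behind published paired
  AUC p-values is often unnamed); a paired bootstrap (2000 resamples,
  fixed seed) is available as `method = "bootstrap"`.
* `binormal_auc()` gives the closed form
  $\Phi(|\mu_1-\mu_2|/\sqrt{\sigma_1^2+\sigma_2^2})$ used as an analytic
  oracle: on the default DDC group distributions it gives ≈ 0.974, and
  real cohorts reporting lower empirical AUCs for the same moments are
  simply telling you the data are not normal.

## The synthetic cohort

The generator (`generate_cohort()`, `run_study()`) emulates the study
conditions the analysis assumes:

* **Group structure**: 58 responders, 26 non-responders.
* **Parameter distributions**: truncated normal per group (truncation at
  the model invariants, e.g. $\alpha \le 1$), with defaults equal to the
  reported group-level means ± SD of a cervical-carcinoma
  radiochemotherapy cohort (responders: ADC 0.610 ± 0.072, D 0.443 ±
  0.167, D* 6.891 ± 5.588, f 25.318 ± 9.069 %, α 0.912 ± 0.043,
  DDC 0.831 ± 0.141; non-responders: ADC 0.980 ± 0.089, D 0.843 ± 0.235,
  D* 8.820 ± 6.456, f 32.356 ± 10.723 %, α 0.612 ± 0.235, DDC 1.257 ±
  0.167; diffusivities ×10⁻³ mm²/s). Parameters vary *between* patients
  with the full reported SD and *within* each tumor with a small 5%-CV
  multiplicative jitter — patient-level dispersion is what cohort tables
  report; true within-tumor heterogeneity is unreported, so the 5% CV is
  a modeling choice exposed in the configuration.
* **Signals and noise**: each phantom voxel's decay comes from a chosen
  forward model and is corrupted by Rician noise (magnitude-image
  convention: $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$), with per-b
  standard deviation $\sigma_b = S_0 / (\mathrm{SNR}_{b0}
  \sqrt{\mathrm{NEX}_b/\mathrm{NEX}_{b_0}})$ — NEX averaging enters as
  $\sqrt{\mathrm{NEX}}$ noise reduction. Default SNR 100 at $b=0$.
  $\mathrm{SNR} = \infty$ reproduces the forward model exactly.
* **Generating model per family**: SEM is the default generating model
  (it is the family that fits real tumor decays best); when IVIM or mono
  parameters are the quantity of interest, signals are generated from
  that model instead, and `run_study()` therefore builds one phantom
  cohort per family sharing the group structure. Fitting one family to
  another family's decay induces systematic distortion (a mono ADC
  fitted to a low-α stretched decay is not the ADC the table distribution
  describes), which would defeat the purpose of anchoring the simulator
  to reported group distributions. The generating model is recorded in
  each cohort's manifest.
* **Phantom geometry**: each patient is a small multi-slice grid
  (default 8×8×3) with 48 tumor voxels split ~1:2:1 across three slices,
  so per-slice ROI areas differ and the area-weighted VOI rule is
  genuinely exercised. These sizes make the full 84-patient,
  three-family study run in well under a minute on one core while
  leaving per-voxel noise realistic; they are phantom choices, not
  claims about tumor volumes.
* **Trajectories**: per-category diameter paths on the quarterly visit
  grid (1.5, 3, 6, 9, 12, 15, 18 months) whose 12-month change is drawn
  inside the category's band with a safety margin (PR: 35–75% shrinkage;
  SD: −25% to +15%; PD: +22% to +50%; CR: linear disappearance at a
  visit ≤ 12 months), so classification closure holds by construction
  and is verified by test.
* **Covariates and readers**: categorical covariates are drawn from the
  reference cohort's printed per-group proportions. (Those printed
  responder tumor-size counts sum to 40, not the group's n = 58 — an
  inconsistency in the source table; the proportions are used as
  printed.) Responders split CR/PR 35/65 and non-responders SD/PD 80/20
  — the source reports no category-level counts, so these are modeling
  choices. Two-reader repeat measurements are simulated as independent
  Gaussian perturbations of the true VOI values (default 5% CV), which
  drives Lin's CCC from 1 (no reader noise) toward 0.

Every generator output is a pure function of its configuration and seed.

## What passing tests show — and what they do not

The phantoms establish that the estimation chain is *correct*: noiseless
round-trips recover parameters to 0.01% across the plausible parameter
space; at SNR 100 the fitted group means track the generating means
within a few percent; estimator bias and dispersion shrink monotonically
with SNR; and the statistics agree with independent brute-force oracles.
They do not establish clinical performance: real tumors have partial
volume, motion, susceptibility distortion, perfusion T2 effects (f is
not T2-corrected here either), and non-normal parameter distributions,
none of which the phantoms contain. Empirical AUCs on real cohorts will
differ from the binormal closed form for exactly that reason.

## Known limitations

* No eddy-current/motion correction, registration or denoising; masks
  are inputs, not computed.
* $D^*$ estimates are intrinsically noisy at clinical SNR (wide sampled
  SD, bound flags); this mirrors the known instability of
  pseudo-diffusion estimation rather than a defect of the fitter.
* The phantom geometry is a labeled block, not anatomy.
* Diffusion-tensor and kurtosis models are out of scope.
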