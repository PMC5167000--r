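---
title: "Methods: stage-stratified cortical atrophy rates and hemispheric asymmetry"
author: "cortasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-stratified cortical atrophy rates and hemispheric asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortasym)
```

## The scientific problem

Parkinson's disease (PD) is clinically asymmetric, and several lines of
evidence suggest the left hemisphere is more susceptible to early cortical
degeneration than the right. A practical way to study this with a single
MRI per patient is a cross-sectional design: collect regional cortical
thickness (mm, FreeSurfer Destrieux parcellation) for a large cohort with a
wide spread of disease durations, split the cohort into an Early stage
(duration at or below 10 years since first motor symptom) and a Late stage
(above 10 years), and treat the regression of thickness on duration within
each stage as an estimate of the regional *atrophy rate* in mm/year.

`cortasym` implements that analysis as a reusable, seeded pipeline:

1. **Staging** — `assign_stage()` labels patients Early/Late at a duration
   cutoff (default 10 years; the boundary itself is Early, following the
   "at most 10 years" staging rule).
2. **Group comparison** — `compare_regions()` tests, per region, whether
   mean thickness differs between Early and Late patients (Welch two-sample
   t-test; difference oriented Early − Late so positive values mean the
   Late group is thinner), controlling the false discovery rate at 0.1
   separately within each hemisphere (Benjamini–Hochberg).
3. **Rate estimation** — `atrophy_rates()` fits, per region and stage, the
   OLS slope of thickness on duration, with a percentile bootstrap CI
   (patients resampled with replacement within the stage), and the
   bootstrapped Early − Late slope difference.
4. **Laterality** — `duration_correlation()` and
   `paired_hemisphere_test()` probe whether left-lateralized findings
   survive restriction to handedness subgroups and to patients with
   markedly lateralized motor symptoms.

## Model and assumptions

For region $j$, stage $s \in \{E, L\}$ and patient $i$ in that stage, the
working model is a linear segment with homoscedastic Gaussian noise:

$$y_{ij} = \beta_{0,js} + \beta_{1,js} \, d_i + \varepsilon_{ij}, \qquad
\varepsilon_{ij} \sim N(0, \sigma_j^2),$$

where $d_i$ is disease duration (years) and $\beta_{1,js}$ is the atrophy
rate (mm/year; negative = thinning). The two stage segments are fitted —
and, in the synthetic generator, simulated — independently: no continuity
is imposed at the cutoff, because the design estimates each stage
separately and asserts nothing about the joint trajectory. Because each
patient contributes one time point, the "rate" is a cross-sectional
estimate; cohort effects (e.g. faster-progressing patients reaching
assessment earlier) are not distinguishable from true within-patient
change. That is an inherent limitation of the design, not of the
implementation.

The Early − Late slope contrast $\Delta_j = \hat\beta_{1,jE} -
\hat\beta_{1,jL}$ is assessed with a case-resampling bootstrap: each
replicate independently resamples patients with replacement within Early
and within Late, refits both slopes, and records their difference. The
95% percentile interval of the replicates gives the CI, and significance
follows the **CI sign rule**: both endpoints negative ⇒ significantly
faster Early-stage atrophy; both positive ⇒ significantly faster
Late-stage atrophy. The sign convention is fixed as Early − Late
throughout (a negative slope difference means the Early stage thins
faster), and the same orientation is used for the mean-thickness contrast.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `cutoff` | 10 | years | stage boundary, inclusive on the Early side |
| `n_boot` | 2000 | replicates | percentile CIs stabilize well below this; ≥ 200 enforced |
| `alpha` | 0.05 | — | CI level complement (95% CIs) |
| `q` | 0.1 | — | per-hemisphere BH FDR level |
| `threshold_sd` | 1 | cohort SDs | motor-laterality subgroup selection |
| `seed` | — | — | master seed; all randomness derives from it |

Choices the analysis leaves open were resolved as follows and are recorded
in every run's metadata so they are auditable:

* **Welch vs pooled t** — Welch by default (robust to unequal group
  variances, the safer default for unequal group sizes); pooled available
  via `var_equal = TRUE` for sensitivity analysis.
* **FDR procedure** — Benjamini–Hochberg step-up, the field default for
  region-wise control, applied independently per hemisphere so decisions
  in one hemisphere can never depend on p-values in the other.
* **Bootstrap flavour** — case resampling of patients stratified by stage
  (robust to heteroscedasticity and x-randomness), percentile CIs rather
  than BCa (simpler, adequate at these group sizes; see the coverage
  experiment in the test suite).
* **Paired vs unpaired hemispheric test** — within-patient left − right
  differences with a paired t-test: hemispheres of the same patient are
  strongly correlated, and an unpaired test would be inconsistent with
  per-side summary statistics computed on the same patients. The unpaired
  variant is available (`paired = FALSE`) for sensitivity checks.
* **Motor laterality index** — right-extremity item mean minus
  left-extremity item mean, so negative values indicate predominant
  left-sided symptoms; selection beyond `threshold_sd` SDs uses the mean
  and SD of all patients with score data, not of any subgroup.

## Numerical choices and degenerate inputs

* OLS slopes use the closed-form centered formulas; they agree with the
  normal-equations solution to numerical precision and are exact on
  collinear input. The closed form is vectorized across bootstrap
  replicates, which keeps full pipelines and simulation studies fast.
* Percentile endpoints use `quantile(type = 7)` (R's default,
  interpolation-based). On noise-free data every resample gives the same
  slope and the CI collapses to a point, which the sign rule handles
  correctly.
* A bootstrap resample whose durations are (numerically) constant cannot
  be refitted; such resamples are redrawn, with a capped number of passes
  (default 100) and a tally reported in the output
  (`degenerate_redraws`). With realistic group sizes redraws are rare.
* Per-estimate bootstrap seeds are derived from the master seed plus a
  stable string hash of the thickness column key, so adding, dropping or
  reordering regions never perturbs the results of other regions.
* Zero-variance edge cases are defined rather than left to error where a
  definition is natural (identical groups ⇒ difference 0, p = 1; an
  all-symmetric cohort ⇒ no laterality selection, with a warning), and are
  errors where no definition exists (constant durations; zero-variance
  correlation input).
* Handedness values outside R/L are mapped to the explicit category NR
  (not recorded), never imputed.

## The synthetic cohort generator

No patient-level data accompany this design, so validation rests on a
generator (`sim_config()`, `generate_cohort()`) that emulates the data
*structure* the analysis assumes: durations uniform within each stage's
range (defaults 2.2–9.9 and 10.1–27.1 years, with 109 Early and 96 Late
patients, matching the emulated cohort's shape), piecewise-linear regional
thinning with independent stage segments, homoscedastic Gaussian noise per
region, and clinical covariates (sex, onset/assessment ages, handedness
R:L:NR proportions, UPDRS-III Off/On totals, and 8 integer 0–4 extremity
item scores per side with a configurable left/right mean shift for
lateralized patients). `generate_null_cohort()` builds null/signal
mixtures — null regions with identical distributions in both stages —
with ground-truth flags for FDR calibration.

Defaults that are assumptions rather than reported quantities: the
within-region noise SD (0.15 mm — a typical between-subject spread for
regional FreeSurfer thickness; the emulated study does not report it), the
baseline thickness (2.7 mm), the uniform duration law (only ranges and
means are reported; uniform is the least-structured law consistent with a
range), and the 8-item extremity score set (the UPDRS-III items that
constitute "extremity" scores are not enumerated; the count is
configurable).

What the generator does **not** emulate — and hence what passing
recovery/calibration tests do and do not show: spatial correlation between
regions (each region's noise is independent), non-Gaussian or
heteroscedastic measurement error, nonlinear trajectories, correlation
between clinical covariates and thickness (age, sex and UPDRS are
decorative unless configured), and segmentation/registration artefacts.
Tests passing on this generator demonstrate that the estimators recover
the parameters of the model they assume at the stated precision — not that
the model is true of real cohorts.

## Simulation experiments

The test suite and `scripts/acceptance.R` run the validation experiments
at these problem sizes, chosen to keep Monte-Carlo error small relative to
each check's tolerance:

* **CI coverage** — 1000–1500 replicate cohorts (60 + 60 patients,
  noise 0.15 mm, distinct true rates per stage), `n_boot = 1000`;
  the empirical coverage of the 95% percentile CI for the slope
  difference is compared with the nominal level within ±2 percentage
  points.
* **FDR calibration** — 500 replicates of a 60-null + 15-signal per
  hemisphere mixture (40 + 40 patients), BH at q = 0.1 per hemisphere;
  the mean false-discovery proportion must not exceed q beyond its
  Monte-Carlo margin.
* **Parameter recovery** — single cohorts of n = 5000 per stage (noise
  0.1–0.25 mm): published rate, contrast and correlation values used as
  generating truths must be recovered within ±0.005 mm/year, ±0.01 mm and
  ±0.02 respectively.
* **Oracle equivalence** — ≥ 1000 randomized small cases: OLS, Welch t,
  paired t, Pearson and BH outputs agree with independently coded
  brute-force implementations to 1e−10.

## Known limitations

* Cross-sectional "rates" conflate within-patient change with cohort
  composition; only a longitudinal design can separate them.
* The percentile bootstrap is first-order accurate; at 60 patients per
  stage its measured coverage is a fraction of a percentage point below
  nominal (see the coverage experiment), which is acceptable here but
  would matter for much smaller strata.
* Per-hemisphere FDR control treats regions as exchangeable within a
  hemisphere and ignores spatial dependence between neighbouring regions;
  BH remains valid under positive dependence, but the effective number of
  independent comparisons is smaller than the region count.
* The Destrieux label list shipped with the package contains the 74
  cortical sulco-gyral parcels per hemisphere; counts of 75 in the
  literature include the non-cortical medial-wall label, which has no
  meaningful thickness. Nothing in the pipeline depends on the count.
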