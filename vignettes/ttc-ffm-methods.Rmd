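---
title: "Estimating fat-free mass from hand-to-hand bioimpedance: models, simulation design and numerical choices"
author: "ttcbia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fat-free mass from hand-to-hand bioimpedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcbia)
```

## The problem and the two models

Whole-body fat-free mass (FFM) is the quantity clinicians and
body-composition researchers actually want from a bioelectrical
impedance analysis (BIA) measurement. Reference methods (DEXA) are
accurate but expensive and unsuited to frequent use; wrist-worn
hand-to-hand impedance meters are cheap and wearable but measure only
the upper-body current path.

`ttcbia` implements two linear FFM estimators for hand-to-hand BIA:

* the **single-cylinder (SC)** model, the classic empirical approach:
  the body is treated as one conductor of length `height`, so FFM is
  regressed on the bioimpedance index `BI = height^2 / R` (with `R`
  the resistance, i.e. the real part of the measured impedance),
  plus sex, age and total body mass (TBM) to absorb population
  structure the single-cylinder geometry cannot express;

* the **two-truncated-cones (TTC)** model, which replaces the
  population covariates with measured upper-limb geometry: each arm is
  a circular frustum whose base and top circle circumferences are the
  shoulder and wrist circumferences and whose height is the arm
  length. Its regressors are total arm volume, BMI, TBM and BI.

The published fixed-coefficient equations are available as immutable
presets:

```{r presets}
ffm_sc_published()
ffm_ttc_published()
```

Two conventions in these presets are genuinely underdetermined by the
source material and are therefore explicit, documented choices:

* **Arm-volume units.** The TTC coefficient 182.858 is only
  dimensionally sensible if arm volume is expressed in m^3:
  evaluation at typical population means then gives ~49 kg, close to
  the population mean FFM, whereas cm^3 would give values of order
  10^6 kg. The preset therefore consumes m^3, and
  `predict_ffm_ttc(units = "cm3")` performs the conversion explicitly.
  Internally every length is cm and every volume cm^3; the single
  m^3 conversion happens at the equation interface.
* **Sex coding.** Male = 1, female = 0, chosen because the positive
  sex coefficient then raises predicted FFM for males, consistent with
  physiology. The coding is configurable by supplying a different
  feature column; it is never silently inferred.

## Anthropometric and biophysical primitives

The frustum volume is computed directly in circumference terms,

$$V = \frac{h\,(C_1^2 + C_1 C_2 + C_2^2)}{12\pi},$$

because circumferences are what a tape measure yields; radii are never
materialised. The matching conductor resistance for a frustum of
resistivity $\rho$ with linearly varying radius is

$$R = \frac{4\pi\,\rho\,h}{C_1 C_2},$$

the integral of thin-slab resistances. Both reduce to the cylinder
formulas when $C_1 = C_2$, and both are checked in the test suite
against numeric integration of the linear-radius solid of revolution
at relative tolerance 1e-9. The hand-to-hand path is the series sum of
segment resistances; the torso term defaults to zero because its large
cross-sectional area makes its resistance small compared with the
arms. Only resistance is modelled: the source measurements regress on
the real part of impedance, and reactance/phase-angle modelling is out
of scope.

The *arm-volume impedance proxy* `V x TBM/FFM` ties geometry to
composition: at fixed geometry a fatter subject (larger TBM/FFM)
presents a higher resistance because less of the limb conducts.
`fit_proxy()` quantifies this with an OLS fit of measured resistance on
the proxy.

## Training and bootstrap out-of-bag evaluation

`fit_ols()` is ordinary least squares (via `stats::lm`) wrapped so the
result is the same `ffm_model` container as the published presets —
trained and published equations are evaluated, serialised and compared
by identical code paths. Rank-deficient designs are an error naming
the collinear columns, never a silent drop.

`bootstrap_oob()` implements the evaluation scheme identified by the
reported mean training-set size: drawing a size-n resample with
replacement from n = 42 subjects leaves on average
$n(1-(1-1/n)^n) \approx 26.73$ distinct subjects in-bag and
15.27 out-of-bag, matching the reported 26.75 / 15.25 split. Each
replicate fits on the resample and scores r^2, MAPE and maximal
absolute residual on the out-of-bag subjects; metrics are summarised
as mean ± SD over replicates and the reported coefficients are the
replicate means. Numerical and procedural choices:

* Replicates with an empty out-of-bag set or a rank-deficient in-bag
  design are redrawn (and counted) rather than skipped, keeping the
  replicate count exact; at n = 42 the empty-OOB probability is
  ~$10^{-16}$, so redraws are essentially never observed.
* MAPE is stored as a fraction (0.052, not 5.2%); rendering as a
  percentage is a reporting concern.
* Out-of-bag r^2 is skipped (NA) for the rare replicate whose OOB
  target variance is zero; with continuous FFM this does not occur in
  practice.
* The default replicate budget is 10,000 — at study scale the metric
  means are stable to ~1% well before that — with larger budgets
  available by argument.
* `condition_sweep()` derives each grid cell's seed deterministically
  from the master seed and the cell's (model, frequency, position)
  label, so per-cell results are independent of sweep order and
  subsetting.

The five replicate readings of a condition are collapsed by the
median before any modelling (`aggregate_readings`); the aggregation is
pluggable, and the median was chosen for robustness to a single
outlying replicate since the original protocol does not state how
replicates were combined.

## Bland–Altman agreement

`bland_altman()` uses the standard definitions: differences
`d = estimate - reference`, bias `mean(d)`, limits of agreement
`bias ± 1.96 sd(d)` (sample SD), `SE(bias) = sd/√n` and
`SE(LOA) = sd·√(3/n)` for the normal-theory confidence intervals.
Published agreement figures in this literature sometimes print LOA
symmetric about zero despite a nonzero bias, which cannot arise from
these formulas; this package implements the textbook definitions
rather than reverse-engineering any particular figure.

## What the synthetic cohort emulates — and what it does not

No subject-level data were published for the study population this
package targets, so `generate_cohort()` draws cohorts whose *marginal*
structure matches the published summary table: per-sex truncated
normals for age, height and body-fat fraction (male fat
20.35 ± 7.55 %, female 33.18 ± 5.9 %, truncated to the reported
whole-cohort fat range), with the published ranges as truncation
bounds. The joint structure is necessarily the package's own model:

* BMI is generated as a per-sex base plus 20 kg/m^2 per unit fat
  fraction plus jitter, and TBM is derived as `BMI x (height/100)^2`,
  keeping height, TBM and BMI mutually consistent with the published
  marginals (TBM 69.56 ± 11.29 kg at n = 42 lands within 2 SE).
* Sex is assigned by stratified allocation (exactly
  `round(n x sex_ratio)` males, shuffled), mirroring the emulated
  study's balanced 21/21 recruitment; independent Bernoulli assignment
  is available as an option but adds sex-count noise that dominates
  cohort-mean variability at n = 42.
* Arm geometry follows linear allometry: shoulder circumference
  `base_sex + 0.03 height + 60 fat`, wrist
  `5.5 + 0.05 height + 5 fat`, arm length `0.32 height`, each with
  Gaussian jitter plus a small per-side asymmetry term. The
  coefficients were calibrated once so the cohort mean total arm
  volume matches the published 6109 cm^3 and so that body size moves
  arm volume and arm resistance coherently.
* Impedance is produced by the package's own forward physics: series
  frustum resistance with per-subject resistivity
  `rho = 65 x (1/(1 - arm fat))^4.5` Ohm cm at 50 kHz. The female arm
  fat fraction is the whole-body fat fraction minus 0.08, reflecting
  the more peripheral (gynoid) female fat distribution; without this
  the female cluster sits far above the male resistance–proxy trend
  and the pooled proxy fit collapses. The exponent and offset were
  calibrated once against the published 50 kHz thenar resistance
  (562 ± 138 Ohm) and proxy determination (r^2 ≈ 0.78–0.79); the
  defaults land at ~562 Ohm and r^2 ≈ 0.76–0.87 across seeds.
* Frequency enters only as a resistivity scale (1.08 / 1.00 / 0.95 at
  10/50/100 kHz), reproducing the reported ordering of resistance
  with frequency; no dielectric dispersion model is attempted.
  Electrode position enters as an additive path offset — position a
  (fingers) is the longest path and gets +30 Ohm; position b gets a
  negative offset and by far the largest noise.
* Per-condition noise SDs (8–200 Ohm) were calibrated so the
  *relative model quality* across the 3 x 3 grid echoes the published
  pattern: 50 kHz at the thenar clearly best, position b and
  100 kHz/thenar worst. This deliberately trades fidelity of the
  per-condition population SDs for fidelity of the quality ordering —
  both cannot be matched at once, and the ordering is what the
  downstream analysis consumes. Replicate noise is 3 Ohm.
* The reference FFM column carries 0.5 kg of Gaussian measurement
  noise around the generator's true FFM.

A single `noise_scale` multiplies every noise SD, so noise-free
cohorts (`noise_scale = 0`) are exact: replicates collapse to
identical readings and the reference equals true FFM. With
`ffm_rule = "ttc_published"` the generator's FFM rule is the published
TTC equation evaluated on noise-free features, which is what the
pipeline-closure test exploits: agreement bias and LOA half-width
shrink to zero monotonically as `noise_scale` goes to zero.

**What passing tests do and do not show.** The generator reproduces
published marginals, the forward physics, and the quality ordering of
measurement conditions. It does not reproduce the real joint
dependence among height, mass, arm geometry and impedance (unknown
beyond marginals), inter-observer measurement error, electrode-skin
contact effects, or hydration status. Synthetic-cohort results
therefore validate the *machinery* — estimators, resampling,
agreement — not the clinical accuracy of any equation on new
populations.

## Problem sizes and simulation budgets

Tests and the acceptance script run at the scale the inference targets:
cohorts of n = 42 (the emulated study size) for metric and agreement
checks, 100,000 resamples for the resampling-scheme constants, and
10,000 bootstrap replicates per grid cell. The condition-ranking check
uses an n = 120 cohort: at n = 42 a single cohort's best-condition
ranking is genuinely within subject-sampling noise even though the
expected ordering is clear — itself a useful observation about
single-study condition comparisons at this sample size — while at
n = 120 the ranking is stable across seeds. Coefficient-recovery
coverage uses 200 Monte-Carlo cohorts with a 2.8 kg residual SD,
comparable to the residual scale implied by the published limits of
agreement (5.517/1.96 ≈ 2.8 kg).

## Known limitations

* Resistance only: no reactance, phase angle, or multi-frequency
  dispersion modelling, so hydration and electrolyte effects are
  invisible to the models.
* The published equations are applied as printed; the package never
  refits or "corrects" them, and newly trained coefficients live in
  separately named `ffm_model` objects.
* Bland–Altman here is the classical (constant-bias) form; no
  proportional-bias regression extension.
* The synthetic generator's allometry and resistivity constants are
  calibration targets, not measurements; they live in `cohort_spec()`
  arguments precisely so users can replace them.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
gen <- generate_cohort(cohort_spec(seed = 1))
validate_cohort(gen$cohort)

feats <- derive_features(gen$cohort, frequency = 50, position = "c")
bs <- bootstrap_oob(feats, feats$ffm_ref,
                    c("arm_volume", "bmi", "tbm", "bi"),
                    n_boot = 10000, seed = 2, model_kind = "TTC")
bs

ba <- bland_altman(predict(bs$model, feats), feats$ffm_ref)
ba
plot(ba)
```
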