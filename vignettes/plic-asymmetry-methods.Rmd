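---
title: "Methods: PLIC asymmetry statistics, combination validation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLIC asymmetry statistics, combination validation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plicasym)
```

## The scientific problem

Supratentorial ischemic stroke damages the corticospinal tract (CST), and
the damage is visible in diffusion MRI microstructural maps as a
difference between the lesioned (ipsilesional) and healthy
(contralesional) hemisphere. The posterior limb of the internal capsule
(PLIC) concentrates the tract's afferent and efferent motor fibres, so
PLIC asymmetry at baseline is a natural candidate biomarker for motor
recovery. `plicasym` implements a complete small-cohort analysis around
that idea: two asymmetry statistics per subject and parameter map, an
exhaustive cross-validation of their association with upper-extremity
Fugl-Meyer (FM-UE) scores at roughly five weeks, group-level
deviation-from-control tests, and lesion-geometry covariates.

## Asymmetry statistics

Let $C$ and $I$ be the voxel-value samples of one parameter in the
contralesional and ipsilesional PLIC.

**Mean difference.** $\Delta_{\text{Mean}} = \bar C - \bar I$, in
parameter units. Simple, interpretable, but blind to changes of spread or
shape.

**Half Kullback-Leibler divergence.**
$$\Delta_{\text{KLD}} = \tfrac12 \sum_{i=1}^{B} p_C(i)\,
  \ln\frac{p_C(i)}{p_I(i)},$$
in nats, on probabilities estimated from a *shared* histogram: $B = 10$
equal-width bins spanning the pooled min–max of $C \cup I$. A divergence
is only meaningful on a common partition, and per-subject pooled-range
placement keeps both samples fully inside the support. Bin membership is
half-open $[e_i, e_{i+1})$ with the last bin closed; this convention
matters because the counts feed the statistic, so it is fixed and tested.

Raw frequencies at $\sim$500 voxels over 10 bins are noisy and can be
zero, which the log-ratio cannot tolerate. Probabilities are therefore
estimated by James–Stein shrinkage toward the uniform target: with
empirical frequencies $\hat\theta_k$ and total count $N$,
$$\lambda^* = \frac{1 - \sum_k \hat\theta_k^2}
  {(N-1)\sum_k (1/B - \hat\theta_k)^2}, \qquad
  p = \lambda^* / B + (1 - \lambda^*)\,\hat\theta,$$
with $\lambda^*$ clipped to $[0,1]$ and the uniform vector returned when
the denominator vanishes (the empirical distribution is already uniform,
or $N = 1$). Shrinkage keeps every bin probability strictly positive
whenever $\lambda^* > 0$ and converges to the empirical frequencies as
$N \to \infty$; both properties are verified by simulation in the test
suite.

**Numerical policy.** $0 \cdot \ln(0/q) = 0$; a bin with $p_C > 0$ and
$p_I = 0$ yields $+\infty$ (representable, and excluded from the log
predictor as missing). An optional $\varepsilon$-floor
(`epsilon` argument, renormalised) exists but is off by default — the
divergence is meant to be unbounded. When the pooled range is zero the
histogram degenerates to one bin, the divergence is exactly 0, and the
result is flagged.

**The ½ prefactor.** The statistic is implemented as the printed
directional half-divergence $\tfrac12 D(C\|I)$. The prefactor is also
consistent with a symmetrised reading
$\tfrac12[D(C\|I) + D(I\|C)]$ whose second sum was dropped; because the
intent cannot be settled from the formula alone, both behaviours are
provided (`symmetrized = TRUE`) and the directional form is the default.
The natural logarithm is used throughout, including for the
log-transformed predictor `log_delta_kld`.

## Combination validation

With nine subjects a held-out validation of a regression line is
impossible in the usual sense, so the analysis uses an exhaustive
combination scheme: all $\binom{9}{3} = 84$ ways of reserving 3 subjects
for testing. Per split, an OLS line is fit to the 6 training points and
scored by normalized RMSE on the 3 test points. Three conventions are
deliberately pinned down:

* **NRMSE normalizer** — the range (max − min) of the observed outcome
  over the full cohort, applied identically to split and final NRMSE.
  On a 0–66 FM-UE scale this yields dimensionless errors of roughly
  0.05–0.18 for informative predictors, comparable across outcomes.
* **Best-fit line** — the split whose test NRMSE is closest (absolute
  distance) to the mean test NRMSE over all 84 splits; ties go to the
  earliest split in lexicographic enumeration order (a $10^{-12}$
  tolerance guards the tie-break against floating-point noise). Its NRMSE
  over all nine points is the reported final NRMSE.
* **Optimism adjustment** — signed:
  $r^2_{\text{adj}} = r^2_{\text{full}} - \frac{1}{84}\sum_s
  (r^2_{\text{train},s} - r^2_{\text{full}})$. Training fits on six
  points are typically optimistic, so the adjustment shrinks $r^2$; a
  training fit worse than the full fit legitimately reduces the
  correction, hence signed rather than absolute differences.

$r^2$ is never computed on 3-point test sets (unstable); test sets are
scored only by NRMSE. The procedure is fully deterministic, and the whole
of it is cross-checked against an independent brute-force implementation
at $n = 5$, leave-one-out, in the test suite.

Both predictors ($\Delta_{\text{Mean}}$, $\ln \Delta_{\text{KLD}}$) are
validated against both outcomes (FM-UE at follow-up, change from
baseline) for every parameter map, via `validate_outcomes()`.

## Group statistics

Deviation from control is tested on per-subject ROI means: paired
two-tailed t-tests within groups (control left vs right; stroke ipsi vs
contralesional) and a Welch heteroscedastic test of stroke ipsilesional
values against controls, per CST region and parameter. For the Welch
comparison each control contributes the mean of its two hemispheres — one
number per control, avoiding double counting; left-only and right-only
modes are available. Welch degrees of freedom stay fractional.

Multiplicity is handled by Holm's step-down adjustment, which controls
the familywise error without a preceding global ANOVA. What constitutes a
family is genuinely ambiguous in this design; the package defines it as
all parameters within one region × test kind, and always reports raw and
adjusted p side by side so either reading can be inspected. Cells whose
test is undefined (zero-variance differences) are reported as missing
rather than aborting the analysis.

## Lesion metrics

Lesion volume is voxel count × voxel volume (mm³) / 1000, reported in mL.
Lesion load is the percent of a region's voxels overlapped by the lesion
mask; the whole-CST load is computed over the *union* of the three
ipsilesional region labels (a mean of per-region loads is the other
defensible convention; the union was chosen because "percent of the
structure" reads most naturally as a single structure). Correlations with
FM-UE outcomes report signed $r$, $r^2$, and the signed $r\,|r|$, since a
signed "r-squared" convention appears in clinical reporting. All mask
operations are voxel-index based on a shared grid; no resampling is ever
attempted, and grid or voxel-dimension mismatches are errors.

## The synthetic cohort generator

The study's patient scans cannot be redistributed, so the generator is a
first-class module that emulates the *statistical structure* the analysis
assumes, with defaults fixed once:

* **Design**: 9 stroke + 9 control subjects; stroke baseline FM-UE ≤ 50
  (inclusion criterion, clamped, warned if the model can violate it);
  baseline scan 3–13 days and follow-up ≈38 ± 9 days post-stroke; FM-UE
  integer-valued on [0, 66].
* **Voxel distributions**: truncated normals on [0, 1] for bounded
  indices (ODI 0.25, FA 0.60, GFA 0.55, RDI 0.40; spreads 0.05–0.08) and
  log-normals for diffusivities (MD 0.80, AD 1.70, RD 0.45 in units of
  10⁻³ mm²/s; natural-scale spreads 0.08–0.20). These are typical adult
  deep-white-matter magnitudes; the supports are the principled part, the
  means are configurable knobs, not claims. 500 voxels per region per
  side, matching the default label-box size so disk round trips are
  exact.
* **Effect model**: each stroke subject draws
  $\delta_j \sim U(0, \delta_{\max})$, $\delta_{\max} = 0.1$; the
  ipsilesional distribution is the contralesional one translated by
  $\pm\delta_j$ (ODI up; FA, GFA, AD down, following the direction of the
  group differences the analysis is designed to detect; MD down and
  RD/RDI up are modeling choices the design does not constrain).
  Follow-up FM-UE is $\text{clamp}(\text{round}(60 - 550\,\delta_j +
  \varepsilon), 0, 66)$ with $\varepsilon \sim N(0, 5^2)$ points, so
  scores span roughly 5–60 across the cohort.
  `calibrate_outcome_noise()` solves this model for the noise that
  produces a chosen generating $r^2$
  ($\text{noise sd} = |b|\,\delta_{\max}/\sqrt{12}\,
  \sqrt{1/r^2 - 1}$).
* **Geometry**: one shared 24 × 24 × 24 label grid (registration is out
  of scope) holding six mirror-symmetric 10 × 10 × 5 boxes — cerebral
  peduncle, PLIC, corona radiata per hemisphere — at 1.9 × 1.9 × 2.1 mm
  voxels. Lesion masks cover an exact floor(fraction × region size)
  voxel count of the target region, so every lesion load is analytically
  known.
* **Controls** have identically distributed hemispheres and no FM scores;
  their "ipsilesional" side is left by convention so all downstream code
  treats the groups uniformly.

All randomness flows from one integer seed; identical configurations
reproduce cohorts bit-for-bit.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatial voxel correlation within an ROI (real
diffusion maps are smooth; effective sample sizes are smaller than voxel
counts), between-parameter correlation within a subject (ODI and FA
changes are generated independently here), region-specific parameter
means, registration and partial-volume error, multimodal lesion-affected
distributions, and any drug-arm effect. Recovery of the injected effect
shows the machinery is correct, not that real PLIC asymmetry predicts
real outcomes.

## Problem sizes and numerical checks

The test suite and the acceptance script run entirely on generated data:
statistic-level oracles on samples of tens of voxels; calibration checks
on 100 cohorts (effect recovery at a generating $r^2$ of 0.85, and a
zero-effect null) and 200 cohorts (type-I error of the paired tests,
1200 null cells against binomial 99% bounds); pipeline round trips on a
20³ grid with 4³ boxes. These sizes were chosen to make the statistical
assertions sharp at interactive runtimes; the generator scales to larger
grids and cohorts unchanged.

## Known limitations

* The KLD at 10 bins and 500 voxels is biased upward for nearly identical
  distributions (shrinkage mitigates but does not remove this); the log
  transform makes the predictor scale-sensitive near zero divergence.
* With $n = 9$, the optimism-adjusted $r^2$ has large sampling
  variability; the recovery corridor in the acceptance checks
  ([0.70, 0.95] median over 100 cohorts at a generating $r^2$ of 0.85) is
  a sanity band, not a point claim.
* Exhaustive $\binom{n}{3}$ enumeration is intended for small cohorts;
  beyond $n \approx 20$ the split count grows quickly and a sampled
  scheme would be preferable.
* The pipeline requires all volumes of a subject on one grid; it will
  not resample, by design.
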