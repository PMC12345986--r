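---
title: "Growth-inflection analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-inflection analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigrowth)
```

## The growth model and its landmarks

`pigrowth` models pig body weight during the fattening period with the
three-parameter logistic curve

$$y(t) = \frac{A}{1 + B\,e^{-Kt}},$$

where $t$ is age in days, $A$ the mature weight (kg), $B$ a dimensionless
shape parameter and $K$ the intrinsic growth rate (1/day). The model
assumes a single sigmoidal growth phase with a symmetric turning point —
adequate for fattening-period records that start around 50 days of age, but
not for neonatal growth or for breeds with strongly asymmetric curves
(a Richards or Gompertz family would then be preferable; the fitting
machinery here is deliberately limited to the logistic form and exposes no
other families).

All landmark quantities are closed forms of $(A, B, K)$:

* **Inflection**: daily gain $y'(t)$ is maximal at $t^\* = \ln(B)/K$, where
  $y(t^\*) = A/2$ and $y'(t^\*) = AK/4$ (the *maximum daily gain*, reported
  in g/day, i.e. $250\,A\,K$ for $A$ in kg).
* **Maximum deceleration**: the growth rate declines fastest at the
  post-inflection root of $y'''$, $t^{**} = [\ln B + \ln(2+\sqrt3)]/K$,
  where $y(t^{**}) = A(3+\sqrt3)/6 \approx 0.789\,A$. Because feed intake
  keeps rising while gain collapses beyond this age, $t^{**}$ is a natural
  economic proxy for the optimal slaughter age.

For the fat-type (Qingyu-style) parameters $B = 20.059$, $K = 0.016$ the
closed form gives $t^{**} = 269.7$ days, matching the published "around 270
days" recommendation. For the lean-type (Yorkshire-style) parameters the
closed form gives $188.4$ days while the accompanying narrative rounds to
"approximately 200 days"; we treat the closed form as authoritative and
regard the published figure as a managerial rounding, so tests assert the
closed form (and its agreement with a 0.01-day grid search), never the 200.

## Fitting

`fit_logistic()` pools all animals of a breed into one population curve —
one row per breed, matching how such growth-model tables are reported — and
minimises $\sum (y_{obs} - y_{fit})^2$ with Levenberg–Marquardt iterations
(`minpack.lm::nlsLM`, SSE tolerance $10^{-10}$, 500 iterations). Fit
quality is summarised by the Pearson correlation between observed and
fitted weights over all points, the only correlation computable from fit
quality alone.

Starting values are self-starting: $A_0 = 1.05 \times \max(y)$, then an
ordinary linear regression of $\log(A_0/y - 1)$ on age gives
$\ln B_0$ (intercept) and $-K_0$ (slope). Positivity of all three
parameters is enforced by optimising on the log scale. Degenerate inputs
are rejected explicitly: fewer than four distinct points is an error, and a
weight range that never crosses the empirical mid-weight triggers a warning
that the asymptote is poorly identified.

**ADG convention.** Per-group "average daily gain" has no universal
definition, and published per-group values are far below the model's peak
gain, so they cannot be instantaneous rates. `adg_table()` therefore
defaults to a *cumulative* convention — gain since 50 days of age divided
by elapsed days — and offers the instantaneous model rate behind a flag.
The cumulative numbers have the right order of magnitude (hundreds of
g/day) but the original definition is not recoverable, so tests treat them
qualitatively only.

## Trait trajectories and the plateau rule

Published trait-versus-weight curves come without equations, so
`fit_trait_curve()` offers the two simplest families able to express "rapid
rise, then plateau": a quadratic and the three-parameter asymptotic
(monomolecular) curve $y = a - b\,e^{-c\,bw}$ with $c > 0$ ($b < 0$ gives a
decreasing, saturating-downwards curve). `model_form = "auto"` picks the
lower AIC. "Plateau" language is made auditable by a single rule: the
plateau weight is the smallest in-range body weight where the magnitude of
the fitted slope drops below `threshold_fraction` (default 0.1) of the
maximum in-range slope. For the asymptotic family this is the closed form
$bw_{min} + \ln(1/\text{threshold})/c$; otherwise a 0.1-kg grid scan is
used, and the two agree within one grid step by construction. A strictly
linear trend never crosses a 10% slope fraction, so linear traits return no
plateau. The threshold is the one genuinely arbitrary constant in the
module; it is exposed as an argument, and plateau weight is monotone
non-increasing in it.

When a trait is *known* (or programmed, in simulation) to follow a
saturating response, fitting the matched asymptotic family rather than
`auto` avoids the bias of a quadratic approximation near the range ends;
validation of plateau accuracy therefore forces the asymptotic family.

## Trait screening

Weight groups are half-open 10-kg bins, eight per breed, anchored at the
post-inflection range start (80 kg lean, 60 kg fat). The trend call for
each trait is a two-part gate: a one-way ANOVA across weight groups at
$\alpha = 0.05$ (Tukey HSD available for pairwise structure; Student's
t-test when only two groups remain), and the sign of the Pearson
correlation with body weight decides "up" versus "down". Without
significance the trait is "unchanged". The published screening pipeline
does not state which statistic gates the call; this ANOVA-gate +
correlation-sign rule is our documented convention. Multiple-testing
correction is off by default, matching the per-trait $p \le 0.05$ rule of
the original analysis; a Benjamini–Hochberg switch (`p_adjust = "BH"`) is
provided.

Supporting views use stock machinery with fixed conventions: correlations
are pairwise-complete Pearson (constant columns yield flagged `NA`, never a
silent zero); clustering is average-linkage on Euclidean distances of
z-scored (sample SD, $n-1$) group means — the original online tool's
settings are unrecoverable, so these defaults are declared, not inferred;
PCA is on centred, z-scored traits with mean imputation (warned) for
missing values and a deterministic sign convention (largest-magnitude
loading positive).

## Relative expression

`delta_delta_ct()` implements the standard Livak workflow: technical
replicates averaged at the Ct level, $\Delta Ct = Ct_{target} -
Ct_{reference}$ per sample, $\Delta\Delta Ct$ anchored to the *mean*
$\Delta Ct$ of the calibrator group (per-pair matching is not attempted),
fold $= 2^{-\Delta\Delta Ct}$. Group summaries report $2^{-\overline{\Delta\Delta
Ct}}$ — the geometric-mean fold — so the calibrator group's fold is exactly 1
by construction; the arithmetic mean of per-sample folds is Jensen-biased
upward and is deliberately not the headline number, though per-sample folds
(and their SD) are returned. The reference gene is configurable
(`GAPDH` in the simulator) since the original assay's housekeeping gene is
an appendix-level detail.

## What the synthetic generator emulates — and what it does not

`synthetic_herd_spec()` encodes the study conditions as defaults:

* **Growth**: population truths $A = 160.493$, $B = 16.901$, $K = 0.022$
  (lean, 400 animals) and $A = 137.948$, $B = 20.059$, $K = 0.016$ (fat,
  126 animals); per-animal asymptotes $A_i = A(1+\varepsilon_i)$ with 5%
  CV; multiplicative 2% measurement noise (weighing error scales with
  size); ages every 20 days from 50 d (to 350 d lean, 400 d fat) — enough
  span to identify the asymptote on both curves.
* **Slaughter design**: per-breed group sizes and mean weights matching the
  published eight-group layout (184 lean, 73 fat animals), Gaussian within
  groups, clipped to the study range.
* **Trait responses**: linear (slope fixed at 1.5 within-group SD per
  10 kg), saturating (asymptotic, lean LMA plateauing at 130 kg and fat IMF
  at 110 kg — i.e. $c = \ln(10)/50$ per kg anchored at the range start) or
  flat, with additive Gaussian noise; carcass weight is derived as
  $bw \times DP/100$ so dressing percentage is internally consistent. The
  programmed direction counts are 10 up / 2 down (lean) and 15 up / 5 down
  (fat). The original trait lists are internally inconsistent about
  fat-type IMF (listed as decreasing in one figure, described as rising to
  a ~110 kg plateau in the text); we follow the trajectory description, so
  fat IMF is a saturating "up" trait and contributes both to the 15-up
  count and to plateau validation.
* **qPCR**: reference Ct $\sim N(20, 0.2^2)$, gene-specific baseline
  $\Delta Ct$, additive stage effects of ±0.75 cycles per weight stage
  (myogenic genes declining with weight in the lean configuration and
  rising in the fat one, adipogenic genes the reverse), 0.15-cycle noise.

It does **not** emulate: feed intake or diet effects, litter/pen structure
or any within-animal correlation beyond the shared asymptote, seasonal or
batch effects, non-Gaussian trait distributions, censoring/missingness, or
genuine biological covariance among traits beyond their shared dependence
on body weight. Passing tests therefore demonstrate that the estimators
recover the structure they assume, at realistic sample sizes and noise —
not that real herds satisfy those assumptions.

## Numerical choices and validation sizes

Determinism: every simulator takes a seed, uses it via `withr::with_seed`
(the caller's RNG stream is untouched) and records it in its output; same
spec + seed gives byte-identical tables. Validation in the test suite uses
the study-scale sizes directly (400 + 126 animals for parameter recovery;
20 replicate slaughter tables for trend recovery; 1000 null replicates of
8 × 10 observations for ANOVA calibration; 10 replicate herds for plateau
accuracy) — all of which run in seconds. Plateau accuracy is assessed by
the Monte-Carlo mean across replicate herds because a single 73-animal herd
estimates the saturation rate $c$ with roughly ±15% error, i.e. ±8 kg on
the plateau weight.

## Known limitations

* One growth family; population-level (pooled) fitting only — no
  mixed-effects per-animal curves, though per-animal records are accepted.
* The plateau rule is threshold-based point detection, without uncertainty
  intervals; changepoint inference is out of scope.
* The trend gate uses uncorrected per-trait tests by default (by design,
  matching the original convention); expect ~5% false-positive calls among
  truly flat traits.
* 2^−ΔΔCT assumes perfect (and equal) amplification efficiency; no
  Pfaffl-style efficiency correction.
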