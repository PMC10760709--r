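---
title: "Energy-optimal walking speeds: model, inference and testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-optimal walking speeds: model, inference and testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkopt)
```

## The scientific question

Preferred (self-selected) walking speed is a standard mobility measure, but
it is usually taken over one straight distance. Daily walking is dominated
by short bouts and turns, and people — with or without lower-limb
amputation — walk slower over short distances and on tighter curves.
`walkopt` treats both effects as consequences of metabolic energy
minimisation: the preferred speed is modelled as the speed that minimises
the energetic cost of the whole task, and the costs of changing speed and
of turning are inferred from how much people slow down.

## The cost model

All quantities are normalised per unit body mass; subject mass is carried
in the data for schema fidelity but never enters the model (the steady-rate
coefficients are in W/kg, and the start–stop kinetic-energy term is written
per kilogram to match). This is deliberate: speeds, not absolute energies,
are the observable.

**Steady walking.** The metabolic rate at constant speed $v$ is quadratic,
$\dot E = a_0 + a_1 v + a_2 v^2$ (W/kg, $v$ in m/s). The package ships
literature treadmill-calorimetry values per group
(`steady_coefficients()`): above-knee amputation (4.97, −5.98, 5.62),
below-knee (3.64, −2.19, 2.89), no amputation (2.22, 0, 1.115). $a_0 > 0$
and $a_2 > 0$ make cost per distance U-shaped; $a_1$ may be negative.

**Short bouts.** A bout of distance $D$ is idealised as: accelerate
instantaneously from rest to $v$, walk the whole distance at $v$, stop
instantaneously. The total cost is

$$E(v) = (a_0 + a_1 v + a_2 v^2)\,\frac{D}{v}
  + a_\mathrm{change}\left(\frac{1}{\eta_\mathrm{pos}} +
  \frac{1}{\eta_\mathrm{neg}}\right)\frac{v^2}{2},$$

with muscle efficiencies $\eta_\mathrm{pos} = 0.25$ for positive and
$\eta_\mathrm{neg} = 1.2$ for negative work (both dimensionless,
`efficiency_params()`), and a dimensionless empirical factor
$a_\mathrm{change} \ge 0$ scaling the kinetic-energy cost of the speed
changes. Setting $\partial E/\partial v = 0$ gives the implicit optimality
condition

$$a_\mathrm{change}\, v^3 \left(\eta_\mathrm{pos}^{-1} +
  \eta_\mathrm{neg}^{-1}\right) / (a_0 - a_2 v^2) = D,$$

whose left side increases strictly from 0 to $\infty$ on
$(0, \sqrt{a_0/a_2})$: the optimum exists, is unique, increases with $D$,
and approaches the steady optimum $\sqrt{a_0/a_2}$ for long bouts. The
instantaneous-acceleration idealisation means the model's "speed" is the
bout-average speed; gradual acceleration/deceleration phases are outside
scope, which limits quantitative (not qualitative) accuracy of
$a_\mathrm{change}$.

**Circles.** Turning at tangential speed $v$ on radius $R$ adds
$a_\mathrm{turn}(v/R)^2$ to the rate ($a_\mathrm{turn}$ in W/kg per
$(1/\mathrm{s})^2$; $v/R$ is the angular rate in 1/s). Cost per distance
is $a_0/v + a_1 + a_2 v + a_\mathrm{turn} v/R^2$, minimised in closed form
by $v_\mathrm{opt} = \sqrt{a_0/(a_2 + a_\mathrm{turn}/R^2)}$ — slower on
tighter circles, approaching the straight-line optimum as
$R \to \infty$.

**Near-optimal bands.** Both landscapes are flat near their minima, so the
package reports the band of speeds within a fraction (default 1%) of the
minimum cost (`near_optimal_band()`): observed speeds inside the band are
practically indistinguishable from optimal.

## Numerical choices

- The implicit optimum is solved with `uniroot` on
  $(10^{-9}, \sqrt{a_0/a_2} - 10^{-9})$, tolerance $10^{-10}$; the bracket
  is guaranteed by monotonicity. $a_\mathrm{change} = 0$ is handled
  analytically (the optimum is $\sqrt{a_0/a_2}$ for every $D$).
- Band endpoints are found by geometric bracket expansion plus `uniroot`
  (tolerance $10^{-8}$); if the cost never exceeds the threshold below the
  configured ceiling the band is reported open-ended rather than invented.
- Predictions depend only on a trial's condition, so they are computed once
  per unique distance/radius and mapped back — this is what keeps the grid
  validation and large-cohort fits fast.
- Degenerate inputs are rejected loudly: $v = 0$ (bout cost diverges),
  non-positive durations, trials with neither distance nor radius.

## Inverse optimization

`fit_coefficients()` minimises the mean squared error between model-implied
optimal speeds and observed trial speeds, pooled over straight and circle
trials with equal weight per trial (so conditions with four trials count
four times). Version 1 frees $(a_\mathrm{change}, a_\mathrm{turn})$;
version 2 also frees $a_2$, which absorbs discrepancies from the
literature steady coefficients, including non-energetic speed-dependent
costs (joint stress, stability). $a_0$ is pinned because the optima are
invariant to scaling all five coefficients; $a_1$ because neither optimum
involves it. Both invariances are asserted numerically in the test suite.

The optimiser is Nelder-Mead (`stats::optim`) on log-transformed free
coefficients (enforcing positivity) from five start points spanning the
validation grid, with a polish restart at the incumbent. Each fit is then
validated against an exhaustive grid ($a_\mathrm{change}$ in [0, 10] step
0.01, $a_\mathrm{turn}$ in [0, 20] step 0.02, $a_2$ in [0.5, 10] step
0.01): a coarse pass at 10× the step followed by a 10× refinement around
the incumbent. Because $a_\mathrm{change}$ affects only straight-bout
predictions and $a_\mathrm{turn}$ only circle predictions for given
$a_2$, the multi-dimensional grid minimum decomposes exactly into 1-D
sweeps; the decomposition is an algebraic identity, not an approximation,
and the decoupling itself is verified against independent 1-D
golden-section fits in the tests. A fitted optimum outside the grid bounds
marks validation inconclusive with a warning instead of silently passing.

## Hypothesis testing

The design is within-subject: per-subject condition means (straight speed
$D/T$ averaged over the four trials per distance; circle speed
$\mathrm{laps}\cdot 2\pi R/T$ per trial, kept per direction and pooled)
feed ten pre-registered one-sided tests — each short distance (4, 6, 8,
10 m) vs the 23 m bout, a positive speed–distance slope over 4–10 m, each
radius (1, 2, 3 m) vs the 23 m bout, a positive speed–radius slope, and
prosthesis-out vs prosthesis-in pooled over radii — plus a post hoc,
uncorrected repeat of the direction contrast in the above-knee subgroup.

The primary p-values are paired subject bootstraps: the statistic is the
mean within-subject difference, subjects (not trials) are resampled with
replacement $10^5$ times, and $p$ is the proportion of resampled means
$\le 0$, floored at $1/n_\mathrm{boot}$ so a p-value of exactly zero is
never reported. Subject resampling (rather than trial resampling) respects
the correlation of each subject's speeds across conditions. Each bootstrap
test carries a paired one-sided t analogue (`stats::t.test`), and both are
Bonferroni-corrected ×10. Slope tests bootstrap the fixed-effects slope,
recomputed per resample from per-subject within-subject cross-products —
algebraically identical to refitting the subject-dummy regression, and
cross-checked against `stats::lm` and a normal-equations solve in the
tests. Subject offsets are fixed effects, and adjusted $R^2$ follows the
standard formula; the estimator for the published analysis was not more
specific than "subject-specific offsets", and dummy intercepts are the
simplest faithful reading. Percent speed reductions are summarised relative
to each subject's 23 m mean (mean ± s.d. across subjects; all, below-knee,
above-knee pools).

## The synthetic cohort generator

`generate_cohort()` emulates the trial design: 7 above-knee and 5
below-knee subjects; straight bouts of 4, 6, 8, 10, 23 m × 4 trials;
circles of radius 1, 2, 3 m for 5, 4, 3 laps, once per direction — 26
trials per subject, 312 in all. Speeds are
$v_{ic} = v_\mathrm{opt}(c)\,e^{b_i}e^{e_{ict}}$ with
$b_i \sim N(0, \sigma_\mathrm{subject}^2)$,
$e \sim N(0, \sigma_\mathrm{trial}^2)$, plus an additive
`direction_effect` (default 0, matching the null pooled direction result)
on prosthesis-out circles; durations are back-computed so the loader's
derived speeds reproduce the generator's exactly. Defaults
$\sigma_\mathrm{subject} = 0.08$, $\sigma_\mathrm{trial} = 0.04$: the
within-study speed summaries report across-subject dispersions of roughly
5–8%, and no within-subject trial variance is published, so these are
plausible placeholders, not estimates. Noise is multiplicative so durations
stay positive. Generating coefficients default to the literature steady
sets merged with the published inverse-optimization estimates per group.
Subject covariates (age, mass, heights, leg lengths, sex, side, daily hours
on legs, years since amputation) are sampled uniformly within the ranges of
the published subject table purely for schema fidelity — they never
influence speeds, since the model fits no covariate effects.

What passing tests on synthetic cohorts do show: the estimation machinery
recovers known generating coefficients (exactly when noiseless, within a
few percent under realistic noise), the battery detects effects that are
present and stays quiet under a null, and the pipeline is deterministic in
its seed. What they cannot show: that real prosthesis users' speeds follow
the lognormal generative model, that the literature steady coefficients
match any particular cohort, or anything about gait mechanics within a
bout — the generator has no velocity profiles, steps or metabolic
measurements.

```{r example}
co <- generate_cohort(synthetic_config(sigma_subject = 0, sigma_trial = 0,
                                       seed = 1))
tr <- cohort_trials(co)
subj <- cohort_subjects(co)
fit_coefficients(fit_spec(1, "below_knee"),
                 tr[tr$subject_id %in%
                      subj$subject_id[subj$level == "BK"], ])
```

## Problem sizes and reproducibility

The shipped tests run fits on 12-subject cohorts (plus one 50-subject,
trial-noise-only cohort for the stochastic recovery check), use 1 000–20 000
bootstrap resamples where the distribution of a p-value matters, and 2 000
replications for calibration properties; these sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping the suite quick.
The full pipeline default remains $10^5$ resamples. All randomness flows
from single integer seeds (the generator derives per-subject draws from its
one seed; the battery derives one recorded seed per test), and reports are
byte-identical across reruns apart from log timestamps.

## Known limitations

- The instantaneous speed-change idealisation biases $a_\mathrm{change}$
  upward relative to a model with gradual acceleration phases.
- Inverse optimization cannot distinguish metabolic from perceptual or
  stability costs; fitted coefficients are "as-if" energetic.
- The version-2 fit leaves $(a_2, a_\mathrm{change}, a_\mathrm{turn})$
  weakly coupled through the shared speed scale; with few subjects the
  ridge can shift individual coefficients while barely changing the MSE,
  which is why the grid validation and the scale/\(a_1\) invariances are
  part of the shipped checks.
- Group fits pool subjects; no subject-level coefficients or mixed-effects
  structure is attempted.
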