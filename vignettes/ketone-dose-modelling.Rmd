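---
title: "Modelling oral 3-HB kinetics and choosing a minimum effective dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oral 3-HB kinetics and choosing a minimum effective dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ketodose)
```

## The problem

3-hydroxybutyrate (3-HB) is the main circulating ketone body. The brain can
switch to it as an energy substrate, and a peak plasma concentration around
0.28 mM is considered sufficient to initiate brain ketone metabolism. An
oral dose should therefore be *as small as possible while still reaching
that peak*: larger doses bring flavour and tolerability costs without a
qualitative benefit. This package models the serum concentration-time
course after a single oral dose, estimates the model from concentration
data, and searches the dose axis for the smallest dose whose simulated
C~max~ reaches the target. A companion module analyses the 2×2 crossover
trial used to test the selected dose.

## The model and its assumptions

A single well-stirred serum compartment with volume of distribution $V_d$
is fed by a gastrointestinal depot holding amount $X(t)$ (mmol):

$$\frac{dX}{dt} = -\frac{V_{max} X}{K_m' + X} - k_a X, \qquad X(0) = \text{dose}$$

$$V_d \frac{dC}{dt} = CL \cdot C_0 + \frac{V_{max} X}{K_m' + X} + k_a X - CL \cdot C, \qquad C(0) = C_0$$

Assumptions worth making explicit:

* **Two parallel absorption routes.** A saturable Michaelis-Menten term
  (transporter-mediated uptake: 3-HB is a substrate of intestinal
  monocarboxylate transporters) and a first-order term (passive/paracellular
  leak). $K_m'$ is the Michaelis constant *times* the gut volume, so it is
  expressed in amount units (mmol) and compared directly with the dose.
* **Endogenous production is constant.** Baseline 3-HB is at steady state,
  so production must equal elimination at baseline: production $= CL \cdot
  C_0$. It is assumed unchanged by the dose (no feedback inhibition of
  ketogenesis over the ~2 h horizon). The production rate is always derived
  from $CL$ and $C_0$, never stored as a separate parameter.
* **Linear elimination.** Clearance $CL$ is concentration-independent over
  the sub-millimolar range involved.
* **Serum ≡ plasma.** The 0.28 mM threshold was reported for plasma; the
  concentration data are serum. No matrix conversion is applied.
* **One gut compartment, no transit delay.** Absorption flux is maximal at
  $t = 0$ and declines monotonically. This matters below: it bounds how
  late and how high a peak the model can produce for a given dose.

Units are fixed throughout: amounts mmol, concentrations mM, volumes L,
time min. Oral doses in grams are converted with the molar mass of the free
acid, 104.10 g/mol, because mM concentrations with L/min clearances force
molar amount units.

## Parameters

| Parameter | Units | Meaning | Typical value here |
|---|---|---|---|
| $CL$ | L/min | systemic clearance | 1.82 |
| $C_0$ | mM | baseline (endogenous) serum concentration | 0.063 |
| $k_a$ | 1/min | first-order absorption rate constant | ~0.02 |
| $K_m'$ | mmol | half-saturation amount of the carrier pathway | small (strong saturation) |
| $V_d$ | L | volume of distribution | 85.7 |
| $V_{max}$ | mmol/min | carrier pathway capacity | ~0.48 |

Setting $V_{max} = 0$ or $k_a = 0$ produces the two reduced variants
(`nonsaturable_only`, `saturable_only`) with 4 and 5 free parameters
respectively against the full model's 6; the counts enter the AIC.

## Numerical choices

* **Integration**: `lsoda` (adaptive, stiff-capable) with rtol $10^{-8}$,
  atol $10^{-10}$; the Michaelis-Menten flux makes the system mildly stiff
  as $X \to 0$. The right-hand side is compiled C, as is usual for
  simulation-heavy pharmacometric code. A third state accumulates the
  absorbed amount so tests can verify mass balance ($X + \text{absorbed} =
  \text{dose}$) rather than assume it.
* **C~max~/T~max~**: discrete maximum on the output grid (default 0.1 min
  out to 240 min for dose finding), refined by maximising a local spline
  interpolant within one grid step; ties go to the earliest time, so a flat
  profile reports its peak at $t = 0$.
* **Non-negativity**: states are clipped at zero only for reporting; an
  integration excursion below $-10^{-6}$ aborts with an error.
* **Estimation**: simultaneous least squares over all dose arms with one
  shared parameter set (including $C_0$), Levenberg-Marquardt on
  log-parameters (positivity without explicit constraints), box bounds
  $CL \in [0.1, 10]$, $C_0 \in [0.01, 0.2]$, $k_a \in [10^{-4}, 1]$,
  $K_m' \in [0.1, 500]$, $V_d \in [5, 500]$, $V_{max} \in [0.01, 10]$.
  Residual weighting is uniform by default (mean profiles carry no stated
  weights); inverse-observation weighting is available.
* **Global search**: the SSR surface is multimodal, so each fit screens a
  seeded Latin hypercube of $10 \times$ `n_starts` candidate points by raw
  SSR, runs the optimiser from the best `n_starts`, then polishes with
  jittered restarts around the incumbent. Everything is a deterministic
  function of the seed in the options.
* **Standard deviations**: linearised covariance
  $\hat\sigma^2 (J^\top J)^{-1}$ on the log scale with $\hat\sigma^2 =
  SSR/(n-p)$, delta-method back-transform. A rank-deficient $J^\top J$
  flags the SDs unreliable instead of failing.
* **AIC**: the least-squares form $n \ln(SSR/n) + 2p$. Only *differences*
  computed inside this package are meaningful. Variant selection prefers
  the lowest AIC and breaks near-ties (within 2) by the lower final SSR —
  the rule used when a reduced model is "comparable by AIC but with higher
  final sum of squares". Because a reduced variant is exactly a boundary
  point of the full model ($k_a = 0$ or $V_{max} = 0$), the comparison
  seeds the full fit with the embedded reduced solutions and, if the
  optimiser still leaves an epsilon behind, adopts the reduced solution as
  the full model's boundary fit — SSR nesting then holds identically.

## Calibration from printed summaries

When only dose-level peak summaries are available — here, C~max~ 0.266 mM
at 30 min after 2 g and 0.289 mM at 45 min after 4 g — the absorption
triplet $(V_{max}, K_m', k_a)$ is recovered by least squares on relative
peak residuals with $(CL, C_0, V_d)$ held at their published estimates,
equal weight on the C~max~ and T~max~ terms. Two constraints (four numbers)
are the minimum for three parameters; fewer is refused.

This calibration is deliberately allowed to fail loudly: with the
disposition parameters fixed, a depot that empties monotonically cannot
push the 2 g peak as high as 0.266 mM at 30 min — the most favourable
profile (constant-rate emptying that finishes exactly at 30 min) caps
C~max~ near 0.23 mM. The optimiser therefore lands at a compromise
(peak times within 2%, peak heights −17%/+11%) and emits a
calibration-infeasible warning carrying the best-found parameters. The
published fit used the full concentration-time curves, of which only these
summaries survive in print; the mismatch is a property of the summaries,
not of the model code. The downstream answer is robust to it: the
calibrated model still brackets the threshold exactly as published (3 g
below 0.28 mM, 3.5 g above).

## Dose finding

C~max~ is strictly increasing in dose for this model (superposition plus a
monotone saturable term), so the minimum dose is found by a scan of
0.5–8 g in 0.5 g steps — the granularity at which the answer was reported —
taking the first dose whose refined C~max~ meets the target (ties count as
reaching it). A bisection refinement to 0.01 g is available; it must agree
with the grid answer to within one step, which the tests check on random
parameter draws. A target at or below $C_0$ returns 0 g with a notice.

## Crossover analysis

Treatment effects in the 2×2 crossover are estimated by a linear mixed
model on change scores (post − pre): fixed effects for sequence, period and
treatment, a random subject intercept (compound symmetry), REML. On
balanced complete data the treatment estimate equals the closed-form
contrast — the mean over sequences of the sequence-wise mean within-subject
active-minus-placebo difference — and the test suite holds the
implementation to that oracle at $10^{-10}$. Degrees of freedom use the
between-within partition, $n_{subjects} - 2$ for the within-subject
treatment contrast; with balanced data the resulting test is exact, which
is why the type-I error and CI-coverage simulations are held to their
nominal 5% and 95% bands. Treatment labels are validated against the
(sequence, period) design cell and inconsistent records are rejected;
incomplete subjects are excluded listwise with a logged count. No
multiplicity adjustment is applied, matching the trial's stated 5%
two-sided threshold per endpoint.

Supporting pieces: the POMS2 total mood disturbance composite (sum of the
five negative subscales minus vigor-activity — linear, so raising vigor by
$\delta$ lowers TMD by exactly $\delta$); pooled-variance two-sample
t-tests for baseline comparisons (Welch optional; a summary-statistic mode
reproduces printed baseline p-values, e.g. the age row gives $p = 0.922$);
Fisher's exact test for the sex ratio, checked in the tests against direct
hypergeometric enumeration.

## What the generators emulate — and what they do not

`generate_serum_profiles` draws per-subject concentrations as the model
prediction times $(1 + \varepsilon)$, $\varepsilon \sim N(0, CV)$, floored
at 0.001 mM, on the study's 7-point schedule (0, 5, 15, 30, 45, 60,
120 min), default 10 subjects per arm and CV 0.30 — the observed SD/mean
ratio at peak (≈0.079/0.266). Proportional rather than additive noise was
chosen because the printed SDs scale with the mean. **Between-subject
kinetic variability is not modelled**: the noise is observation-level only,
mirroring an analysis that fits mean profiles. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under the
stated error model, not robustness to real kinetic heterogeneity,
correlated within-subject errors, or assay nonlinearity. A population
(mixed-effects) extension would be the natural next step and is
deliberately out of scope.

`generate_crossover_trial` draws change scores from the same linear mixed
model the analysis assumes (default: 40 subjects split 20/20, subject SD
10, residual SD 8.5 — giving change-score SDs near 13, the scale of the
published mood-endpoint rows, whose CI half-width implies a residual SD
near 8.4; default effect −4.7, the published TMD difference). Baselines
are drawn independently so the pre/post bookkeeping is exercised.

## Identifiability caveats

Two structural facts shape what "parameter recovery" can mean here:

* **Flip-flop in the first-order limit.** With $V_{max} = 0$ the profile
  is the Bateman function, which is invariant under exchanging $k_a$ with
  $k = CL/V_d$ (with a compensating $V_d$). Noise-free data admit two
  exact global optima; tests assert recovery of the identified quantities
  (the rate pair as a set, $C_0$, and the curve itself).
* **Pathway aliasing.** When $V_{max}/K_m' \approx k_a$, the saturable
  term is nearly linear over the dose range and the two routes are almost
  collinear; a two-dose design then cannot separate them, and $K_m'$ in
  particular is poorly determined (the published fit itself reported a
  $K_m'$ SD close to its estimate). Recovery simulations therefore use a
  strongly saturated truth — the regime the calibrated model occupies —
  and judge bias by the median signed relative error; $k_a$'s replicate-
  to-replicate spread remains wide (~15–25%) even when its systematic
  bias is small.

## Problem sizes

The simulation studies in the tests use: 100 random draws for the
analytic-oracle comparison; 50 replicates for noisy parameter recovery;
100 replicates for variant selection; 2000 replicates for the crossover
type-I error and 500 for CI coverage. These sizes put Monte-Carlo error
comfortably inside the asserted bands while keeping the default test run
on a single desk-scale core.

## Known limitations

* The published fitted absorption parameters and their SDs are in
  supplementary material not available to this package; exact numerical
  equivalence with the original fit cannot be asserted, only the printed
  $CL \approx 1.82$ L/min, $C_0 \approx 0.063$ mM, $V_d = 85.7$ L and the
  reproduced 3.5 g answer.
* Whether the original least-squares objective was weighted, and whether
  $C_0$ was shared across arms, is not stated; this package shares $C_0$
  and defaults to uniform weights.
* The original AIC formula is unknown; only within-package AIC differences
  are interpreted.
* No two-compartment gut, no feedback on ketogenesis, no food effects, no
  plasma/serum conversion, no population variability.
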