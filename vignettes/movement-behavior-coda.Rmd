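---
title: "Modelling change in the 24-hour movement-behaviour composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling change in the 24-hour movement-behaviour composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24)
```

## The problem

A 24-hour day is exhaustively partitioned into sleep, sedentary time
(SED), light physical activity (LPA) and moderate-to-vigorous physical
activity (MVPA). These four durations are *compositional*: they sum to a
fixed total, so an increase in one behaviour is necessarily paid for by
others, and analysing any one duration in isolation (or putting all four
into a linear model) ignores that constraint. `coda24` treats each
person-day as a point on the 4-part simplex and studies how that point
moves across a life transition — the motivating case is the transition to
full-time retirement, observed with a wrist accelerometer worn 24 h/day
for a week at two waves one year apart, in a cohort stratified by gender
and occupation (manual vs non-manual).

## From accelerometer epochs to daily compositions

The processing module consumes *epoch summaries* (default 5-s epochs):
ENMO (the Euclidean norm of acceleration minus 1 g, in mg), the arm
angle in degrees, and per-axis SD and value range over the surrounding
60-min window. The detection rules are:

* **Non-wear**: evaluated on 15-min blocks; a block is non-wear when,
  over its centred 60-min window, at least two of three axes have
  SD < 13 mg, or at least two have range < 50 mg. Partially overlapping
  blocks are resolved at block granularity (each 15-min block is flagged
  as a whole).
* **Sleep**: only inside the diary-logged bedtime-to-waketime window;
  any maximal span of at least 5 min over which no epoch-to-epoch
  arm-angle change exceeds 5 degrees counts as sleep. Sleep is never
  detected outside the logged window, and non-wear during the sleep
  window counts as non-wear, not sleep (the conservative choice).
* **Waking intensity**: SED below 30 mg, LPA from 30 up to (not
  including) 100.6 mg, MVPA at or above 100.6 mg. Boundary semantics are
  closed on the LPA side at 30 and closed on the MVPA side at 100.6.
* **Days** run from each day's logged bedtime to the next day's bedtime;
  no restriction is placed on night duration. A day is *valid* with at
  least 600 min (10 h) of waking wear; participants need at least 4
  valid days at *both* waves to be included.

Non-wear minutes are excluded from all four parts, so
sleep + SED + LPA + MVPA + non-wear = day length exactly (to epoch
resolution) — a partition identity the tests enforce.

## Simplex machinery

With strictly positive parts $x = (x_\text{sleep}, x_\text{SED},
x_\text{LPA}, x_\text{MVPA})$ closed to $\kappa$ (1 or 1440 min):

* **Zero replacement.** Day-level MVPA occasionally rounds to zero
  (sparse, a handful of person-days in a cohort). Zeros are replaced
  multiplicatively: a zero becomes $0.65 \times$ the 1-min detection
  limit and nonzero parts are scaled down so the total is preserved.
  The 0.65 fraction and the limit are configurable; the choice of simple
  multiplicative replacement (rather than a model-based imputation) is a
  documented default, made because the replaced mass is tiny and the
  method is transparent and total-preserving.
* **Perturbation** $x \oplus p = \mathcal{C}(x_1 p_1, \dots, x_4 p_4)$
  is the simplex group operation; the change composition between waves
  is $\text{post} \ominus \text{pre} = \mathcal{C}(\text{post}/\text{pre})$.
* **Compositional mean**: closure of component-wise geometric means,
  rescaled to 1440 min so group centres read as minutes per day.
* **Balance coordinates.** The sequential binary partition used
  throughout is (1) active {LPA, MVPA} vs passive {sleep, SED},
  (2) LPA vs MVPA, (3) SED vs sleep. Row $k$ with $r$ positive and $s$
  negative parts gives
  $z_k = \sqrt{rs/(r+s)}\,\ln\!\big(g(\text{pos})/g(\text{neg})\big)$,
  an isometric log-ratio (ilr) coordinate: positive $z_1$ means activity
  dominates, positive $z_2$ means LPA dominates MVPA, positive $z_3$
  means SED dominates sleep. The transform is implemented through group
  geometric means; the test suite checks it against an independently
  constructed orthonormal basis matrix to $10^{-10}$, and `ilr_inverse()`
  inverts it exactly.
* **Ternary geometry.** The four leave-one-out 3-part sub-compositions
  are mapped barycentrically to the unit triangle. Confidence regions
  for a sub-compositional mean bootstrap the mean, map bootstrap means
  to a 2-D balance basis of the triple (first part vs rest, then second
  vs third — any orthonormal logratio basis yields the same ellipse),
  and draw the ellipse of squared Mahalanobis distance up to the 95%
  chi-square(2) quantile, discretised at 128 boundary points and mapped
  back to the simplex. Degenerate covariance collapses to a point
  region rather than erroring.
* **Outlier screen.** Changes are compared on all six pairwise logratio
  contrasts $\ln\!\big((\text{post}_i/\text{post}_j) /
  (\text{pre}_i/\text{pre}_j)\big)$; a participant is flagged when any
  contrast exceeds a robust z of 3.5 (median/MAD across the cohort).
  The 3.5 cutoff is a package default — the screening idea follows the
  motivating analysis, which excluded a handful of participants after
  inspecting log contrasts without stating a numeric rule — and flagged
  participants are reported, never silently dropped. Screening is
  disabled (with a warning) below 10 participants, where median/MAD
  scaling is meaningless.

## The longitudinal models

Each balance coordinate is modelled separately with a linear mixed
model. Fixed effects by level: level 1 `time + gender + occupation`;
level 2 adds `time:gender + time:occupation`; level 3 the full
`time * gender * occupation` factorial. Coding: `time` is 0 pre / 1
post; reference categories are *woman* and *non-manual*, so a positive
occupation effect on coordinate 1 means manual workers are more active
at baseline. The published table footnote for the middle model lists
`gender:occupation` while the text describes adding the time
interactions; the text's version is the default and the footnote variant
is available via `model2_terms = "gender_occupation"`.

Each participant receives a random intercept and a random slope of time
(correlated by default; an uncorrelated variant is available).
Estimation is REML via `lme4`; CIs and p-values use the Wald normal
approximation, appropriate at these sample sizes. If a random-slope fit
fails to converge it is refit with a random intercept only and flagged.

Two aggregations are offered. The default, `day_level`, keeps every
valid day: with only two waves, a random time-slope variance is not
identifiable from one observation per participant-wave, and day-level
replication makes both variance components estimable. `wave_mean`
collapses each participant-wave to its compositional mean first (by the
geometric-mean property this equals averaging the day coordinates — a
tested identity) and is fitted with a random intercept only. Which of
the two the motivating analysis used is not stated; neither is asserted
as "the" original.

## What the synthetic generator emulates

`simulate_cohort()` draws logistic-normal day compositions: for
participant $i$ in stratum $s$, day $d$,
$z_{id} = \mu_s + b_i + \mathbb{1}[\text{post}](\delta_s + u_i) + e_{id}$
in balance-coordinate space, mapped back through `ilr_inverse()`.
Random effects live in coordinate space because the logistic-normal is
the natural simplex analogue of the models' normality assumptions.

Defaults are anchored to the published cohort wherever it states them:
stratum sizes (308, 164, 54, 25), seven days per wave, stratum means and
change perturbations taken from the published group-mean table
(`reference_group_means()`). Quantities the source does not state are
the package's own calibration, chosen once: between-person SDs
(0.50, 0.42, 0.15) and slope SDs (0.60, 0.50, 0.17) back-solved from the
published fixed-effect CI widths (gender contrasts and time effects
respectively), and day-to-day SDs (0.35, 0.60, 0.20) — invented, with
the LPA-vs-MVPA balance noisiest because day-level MVPA is the most
variable behaviour. Days default to exactly 24 h (observed day lengths
vary roughly 21–28 h in practice; a jitter option exists, off by
default). A scenario helper plants a configurable number of zero-MVPA
person-days (default 6) to exercise zero replacement.

`simulate_epoch_stream()` realizes a target day composition as an epoch
stream honouring every detector definition above (calm arm angle only
inside the sleep block, ENMO drawn inside the correct band per minute,
wear-level window statistics, optional injected non-wear blocks that
overwrite behaviour minutes). It simulates epoch summaries, not 80-Hz
raw waveforms, and schedules behaviours in shuffled 10-min bouts — it
does not emulate diurnal rhythm, posture transitions or autocalibration
error. Passing round-trip tests therefore shows the detectors implement
their definitions faithfully, not that the definitions are accurate on
real accelerometry.

All randomness descends from one integer seed via an internal
seed-splitting helper; no function touches the global RNG state.

## Numerical choices and problem sizes

* Zero-noise simulations reproduce closed stratum means to floating
  tolerance, and the noise-free time coefficient equals the configured
  perturbation balance exactly — both are tests.
* Parameter-recovery experiments use a deliberately *moderate* noise
  setting (between 0.3, within 0.3, slope 0.2 per coordinate, the MVPA
  balances slightly tighter): at 500 participants per stratum and 7
  days per wave this puts the Monte-Carlo SE of the time coefficient
  near 0.006, so recovery of a -0.17 effect is a sharp check. The full
  Table-calibrated noise is appropriate for realism, not for recovery
  experiments, where it would triple the Monte-Carlo error.
* Calibration suites use 200 model replicates (120 participants, 5 days
  per wave) for null CI coverage and 500 replicates (50 samples, 200
  bootstrap draws) for ternary-region coverage; both sizes keep binomial
  error near 1.5 percentage points.
* The default pipeline simulates day-level compositions directly;
  epoch-level simulation is exercised on single weeks (a full cohort at
  5-s epochs would be ~10^8 epochs and adds nothing to the round-trip
  evidence).

## Known limitations

* Epoch streams are schematic (see above); the processing module does
  not parse device binary formats, autocalibrate, or impute non-wear.
* The Wald normal approximation has no small-sample df correction;
  with very few participants, CIs will be slightly anticonservative.
* The outlier screen's 3.5 robust-z cutoff is a convention, not an
  estimate; with heavy-tailed true change distributions it will flag
  legitimate participants.
* Published cohort-specific coefficient estimates are not reproducible
  here (the underlying data are available only on request); what the
  package validates is the machinery — worked-example arithmetic from
  printed tables, oracle equivalences, round trips, recovery and
  calibration under known ground truth.
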