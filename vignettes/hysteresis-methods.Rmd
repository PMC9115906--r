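---
title: "Methods: thermal-challenge analysis and the RT-DMI hysteresis loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-challenge analysis and the RT-DMI hysteresis loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatloop)
```

This vignette documents the statistical and numerical methods behind
`heatloop`: the climate index, the preprocessing pipeline, the linear
relationship battery, the elliptical fit to the rumen-temperature /
dry-matter-intake (RT-DMI) hysteresis loop, and the design of the
synthetic cohort generator used for validation.

## Study design the package models

The package targets climate-controlled experiments with two arms of
paired animals:

* **TC** (thermally challenged): held thermoneutral, then exposed to a
  multi-day cyclic heat challenge, then returned to thermoneutral
  conditions for recovery — three periods (Pre-Challenge days 1–4,
  Challenge days 5–11, Recovery days 12–18, with days 4 and 12 flagged
  as transition days).
* **FRTN** (feed-restricted thermoneutral): held thermoneutral
  throughout, with each animal's feed offer tied one-to-one to what its
  TC partner ate the previous day. This separates the direct thermal
  response from the response to reduced intake.

Measurements are telemetric rumen temperature (10-minute bolus
cadence), observer-scored respiration rate (RR), panting score (PS),
infrared surface temperatures, individual water meters, daily feed
offer/refusal weights, and periodic liveweights.

## Temperature-humidity index

`compute_thi()` implements

$$\mathrm{THI} = 0.8\,T_A + \frac{\mathrm{RH}}{100}\,(T_A - 14.3) + 46.3$$

with air temperature $T_A$ in °C and relative humidity RH in percent.
`classify_thi()` maps THI onto the Livestock Weather Safety Index
bands, extended to half-open intervals so every real THI value gets
exactly one label: Normal (≤ 74), Alert (74, 78], Danger (78, 83],
Emergency (> 83). `build_diurnal_program()` produces the
piecewise-linear daily temperature/humidity program (ramp up from
07:00, plateau 09:00–16:00, trough at 20:00) used by the challenge
chambers and the simulator.

## Preprocessing

* `rr_from_breath_timing()` converts stopwatch timings (seconds per 10
  breaths) to breaths per minute, `600 / s`.
* `sanitize_rt()` removes bolus readings at or below a floor (default
  35 °C; such readings are artefacts of large drinking events or
  transmission faults) and can optionally mask readings within a window
  after large recorded drinking events. Every removal is logged with a
  reason; nothing is dropped silently.
* `dedupe_bolus_transmissions()` collapses the bolus's retransmitted
  trailing history to one record per animal-timestamp. When
  retransmissions disagree, the latest transmission wins (retransmission
  is treated as a correction channel) and the conflict is logged.
* `compute_dmi()` converts as-fed offer/refusal weights to dry-matter
  intake using the ration's dry-matter fraction; refused chaff can be
  treated as consumed or prorated.
* `compute_wc()` differences cumulative water-meter readings into daily
  consumption; the per-animal daily values telescope back exactly to
  the meter span, a conservation property the tests enforce.
* `aggregate_daily()` collapses everything to per-animal daily means
  with per-measure observation counts, joins feed and liveweight, and
  assigns the experimental period to each day.

## Linear relationship battery

`fit_line()` is ordinary least squares of `y` on `x` with the Pearson
correlation and the two-sided t-test on the slope, labelled with the
field's convention (significant p < 0.05, tendency 0.05–0.08). With
exactly two points — as when a rate of change is taken between two
period means — the line is determined but carries no inference, so the
standard error and p-value are `NA` and the label is `"exact"`.
`run_battery()` applies a default specification (RT vs daily max/min
THI and TA; DMI, liveweight, RR, PS, head surface temperature and
water consumption vs RT) per treatment group and pooled, on group-day
means. The `caveat` column records that daily means are treated as
independent observations, which ignores their serial correlation.
`per_day_contrast()` computes per-day Welch t-contrasts between arms,
reporting the difference but suppressing the test (with a flag) for
single-animal or zero-variance groups.

## Elliptical fit to the hysteresis loop

During challenge, RT rises within hours while DMI declines over days;
during recovery RT falls quickly while DMI recovers slowly. The two
time constants open a loop in the (RT, DMI) plane that a straight line
cannot describe — the same RT corresponds to different DMI on the way
in and the way out. The package fits that loop with a direct
ellipse-specific least-squares conic fit.

### Fitting

`fit_conic()` implements the numerically stabilized direct
least-squares method of Halir and Flusser: the design matrix is split
into quadratic and linear blocks, the constraint $4ac - b^2 = 1$
(which forces an elliptical solution) is imposed through a reduced
3×3 eigenproblem, and the unique eigenvector making the constraint
positive is selected. Inputs are conditioned by centring and a single
pooled scale factor (isotropic conditioning). Per-axis scaling is the
more common choice, but it is not rotation-equivariant: rotating the
input points would change the fitted geometry by more than round-off.
Isotropic conditioning preserves exact equivariance — rotating or
translating the data rotates or translates the fit, to near machine
precision — which the test suite checks at 1e-8 on noisy data.

### Geometry and diagnostics

`conic_to_geometry()` converts the implicit conic to centre, semi-axes
and rotation via the eigendecomposition of the quadratic-form matrix,
and computes the four axis-aligned tangency points (e.g. the maximum-DMI
point and the RT at which it occurs) by quadratic elimination. These
are validated against a dense parametric sampling oracle.

`traversal_direction()` applies the shoelace formula to the observed
day-ordered trajectory: a negative signed area is clockwise. A
clockwise loop in (RT, DMI) means intake lags temperature — the
signature of the challenge/recovery asymmetry. Collinear or degenerate
trajectories return `"undetermined"`.

`ellipse_r2()` reports two goodness-of-fit measures: `r2_response`
predicts DMI from RT using the nearer ellipse branch (out-of-range RT
maps to the nearest vertical tangency) and compares squared residuals
to the variance of DMI, matching how an R² is usually read;
`r2_sampson` is based on the Sampson (gradient-normalized algebraic)
distance, a geometry-aware alternative that uses both coordinates.

## Synthetic cohort generator

`simulate_cohort()` produces a full raw dataset — bolus stream,
observer sessions, meters, feed sheets, climate log — from a latent
physiological model, plus the generating ground truth so that recovery
of known parameters can be tested end to end.

The mechanism that creates the hysteresis loop is two first-order lags
with separated time constants:

* hourly RT relaxes toward a THI-driven target with a time constant of
  3 h (`rt$tau_h`);
* daily DMI relaxes toward a target depressed by the previous day's
  mean RT with a time constant of 2.5 d (`dmi$tau_d`).

Because intake responds to yesterday's temperature and recovers more
slowly than RT falls, the day-ordered (RT, DMI) trajectory closes a
clockwise loop for the challenged arm, as the test suite verifies over
many seeds. Observables are linear in latent RT (e.g. RR at 46
bpm per °C RT) plus noise, so the linear battery has a known truth to
recover; coverage of the 95% confidence intervals is checked over 200
seeds.

Key defaults and their rationale:

* `thi_sensitivity = 0.25` °C RT per THI unit above threshold: set so
  that the equilibrium challenge RT of the latent model reproduces the
  observed challenge-peak trajectory (daily mean RT peaking near
  40.6–40.7 °C) rather than overshooting; this is a calibration of the
  generator to the study conditions, fixed before the test suite was
  frozen.
* From day 12 the recovered state is *adapted*, not a return to
  baseline: the DMI target is scaled by 0.88 and the RT target shifted
  down 0.23 °C, so the loop closes at a different point than it opened.
* Pair feeding offers the FRTN partner the TC animal's previous-day
  intake plus 20% (`pair_offer()`, rounding up to the feed-sheet
  increment: 5 kg eaten → 6 kg offered), with a step-down rule that
  limits day-over-day reductions.

Limitations worth keeping in mind: the generator's noise is Gaussian
and independent within a day, animals differ only by random baseline
offsets, and the adapted-recovery step change is instantaneous —
simplifications chosen to keep the ground truth analytically known
rather than maximally realistic.

## Monte-Carlo problem sizes

The validation suite uses fixed problem sizes chosen to balance
statistical resolution against runtime: 50 seeds for structural
(direction/sign) checks, 200 seeds for ellipse-parameter recovery and
confidence-interval coverage, and 1000 replicates for the type-I-error
calibration of the slope test (nominal 0.05, accepted 0.03–0.07). All
simulations are seeded and bit-reproducible; rerunning the pipeline
with the same seed reproduces its output bundle byte for byte.

## Worked example

```{r example, eval = FALSE}
library(heatloop)

# simulate a paired cohort and run the full pipeline
res <- run_pipeline("report", simulate = TRUE, seed = 42)

# the challenged arm's RT-DMI loop
res$ellipses$TC$geometry
res$ellipses$TC$r2
```
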