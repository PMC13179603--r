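---
title: "Methods: growth, adaptation and biosensor statistics for dynamic microfluidic single-cell cultivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth, adaptation and biosensor statistics for dynamic microfluidic single-cell cultivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscc)
```

## The experimental system

Dynamic microfluidic single-cell cultivation (dMSCC) grows yeast
microcolonies in picoliter monolayer chambers (80 × 90 × 4 µm) arranged in
seven parallel arrays, while the perfusing medium is switched between
glucose excess (50 g/L) and glucose limitation (10 mg/L) on a fixed 30 s
period.  The share of each period spent at excess — the *duty cycle* or
excess fraction $f = y/p$, with $y$ the excess duration and $p = 30$ s —
is the independent variable of every condition sweep, stepped by 2 s
between conditions.  Colonies are seeded with 1–3 cells, grown for 4 h
under constant excess, and then exposed to the oscillation until 18 h.
Phase-contrast images are taken every 8 min and fluorescence images every
32 min; a segmentation pipeline turns them into long-format per-cell
per-frame tables, which are where this package starts.

Because medium exchange is fast relative to cellular consumption, the
environment is decoupled from physiology: concentrations in the chamber
are set by the chip, not by the cells.  The outermost arrays never see
the oscillation and serve as constant-excess and constant-limitation
controls; the excess control is the normalization reference for every
metric.

## The chip model

`make_profile()` represents the square wave; each period begins with the
excess phase.  That phase order is our choice — the experiment does not
define one — and it is the natural one: colonies enter the dynamics from
4 h of constant excess, so an excess-first convention avoids a step
discontinuity at onset.

Two physical imperfections of the chip are modelled because the analysis
must be robust to them:

* **Per-array time shift.** The laminar flow boundary needs a finite
  time to traverse the chip width, so each array step away from the
  centre delays the wave by 2 s (`shift_profile()`).  We additionally
  transfer the same 2 s from one phase to the other (left side lengthens
  excess, right side shortens it); a prolongation/shortening of the
  pulse on peripheral arrays is observed in practice but no functional
  form is established, so a ±2 s-per-step transfer is the minimal model
  consistent with the shift itself.
* **Along-array smoothing.** Chambers further from the inlet see a
  low-pass-filtered version of the wave.  `chamber_response()` models
  the chamber concentration as a linear first-order relaxation
  $\mathrm{d}C/\mathrm{d}t = k(n)\,(C_\text{channel}(t) - C)$ with a
  geometrically decaying exchange rate $k(n) = k_0\,\delta^{\,n-1}$
  along the array.  This is deliberately not a flow simulation (no
  advection–diffusion PDE): a first-order exchange is the minimal
  mechanism that reproduces the two observed degradations — duration
  distortion across arrays and amplitude loss along them.  The trace is
  started at the exact periodic steady state (closed form for a
  two-level input), so its time-average equals the duty-cycle-weighted
  mean of the drive, a property the tests check.

`estimate_pulse_metrics()` quantifies a trace the way a dye measurement
would be read: effective phase durations from threshold crossings at 50%
of the *achieved* amplitude (the threshold level is our choice; reported
durations in the field do not state one), the onset shift as the mean
lag of upward crossings against the nominal wave, and a *definition*
index — achieved amplitude over nominal amplitude — for pulse fidelity.
Definition is our construction; it compresses "the profile loses
definition along the array" into a number in $[0,1]$.

Only the first 10 chambers of each array carry a well-defined pulse, so
the ingest step (`filter_chambers()`) keeps exactly those; pooling all
chambers of a condition (`pool_condition()`) creates the unit of
analysis.  Five or more chambers per condition is the analysis
convention; fewer warns rather than fails so that small fixtures remain
usable.

## Growth mathematics

All growth rates are slopes of ordinary least-squares fits of
$\ln(\text{total colony area})$ against time — natural log, so slopes
are specific growth rates in h⁻¹.  Windows are closed-open $[t, t+w)$,
with the onset frame included in the first window.

* $\mu_\max$: `mu_max_sliding()` fits every 3 h window starting at or
  after onset, advancing frame by frame, and keeps the fit with the
  maximal slope (earliest window on ties, for determinism).  Maximum is
  the only reading consistent with calling the result a *maximal*
  growth rate.
* $\mu_\text{ini}$: one fixed fit over the first hour after onset
  (7–8 frames at the 8-min cadence).
* **Adaptation time**: the intersection of the two regression lines,
  $t^\ast = (b_\text{ini} - b_\max)/(s_\max - s_\text{ini})$, minus the
  onset.  It is reported only when a genuine adaptation phase exists:
  $\mu_\text{ini} < \mu_\max$ *and* $\mu_\text{ini}/\mu_\max < 0.9$.
  When the gate fails — including slopes equal within $10^{-9}$ h⁻¹ or
  an intersection before onset — the duration is reported as 0 with
  `gate_passed = FALSE`, so sweep tables stay rectangular; reporting
  layers show adaptation only where the gate passes.  Constant-condition
  controls never report an adaptation: the statistic is defined relative
  to the onset of dynamics, and under measurement noise the gate can
  trigger spuriously on a control.

On a noise-free two-phase colony the estimator is exact: the initial fit
reproduces the first segment, the maximal fit the second, and their
intersection is the construction breakpoint to machine precision.  Under
noise the estimator is positively biased near the gate boundary — the
denominator $s_\max - s_\text{ini}$ shrinks, and the max-window
selection inflates $s_\max$ slightly — which is why replicate means per
condition, not single-replicate maxima, are the reported dose–response
quantity when replicates exist.

Normalization (`normalize_mu()`) divides by the excess control's
$\mu_\max$ of the same experiment, so the control is exactly 1.  The
time-weighted baseline `time_weighted_mu()` is
$f\mu_\text{exc} + (1-f)\mu_\text{lim}$; measured adapted rates above it
indicate physiology beyond concentration averaging.  `fit_monod()` fits
$\mu = \mu_m S/(K_s + S)$ (Levenberg–Marquardt via minpack.lm) against
the duty-cycle-weighted mean glucose $S_\text{eff} = 50f + 0.01(1-f)$
g/L; the covariate choice is ours — the natural time-averaged
concentration — since no covariate is established for oscillating
substrate.  The fit exists to *reject* the concentration-only model: on
the calibrated dose–responses it leaves visible lack of fit.

Count-based growth rates (`fit_log_linear(..., response = "count")`) are
available as a diagnostic; area-based rates are canonical.

## Population statistics

The ATP readout is the QUEEN-2m ratio uvGFP/GFP (higher ≈ more ATP); the
glycolytic-flux proxy is the GlyRNA ratio CFP/RFP reporting
fructose-1,6-bisphosphate (lower ratio ≈ higher flux).  Ratios are
scale-invariant to global illumination, and records with non-positive
channels are skipped and counted.  Grays are assumed
background-corrected upstream (rolling-ball subtraction happens in the
imaging pipeline).

Per condition and timepoint, the statistic is the median and the 25–75%
interquartile range over *all pooled cells* (chambers are pooled, not
weighted equally — the pooled reading of "all observed cells").
Percentiles interpolate linearly between order statistics
(`stats::quantile` type 7); the convention is not fixed by the field, so
we use R's default.  One plotted point per condition is the arithmetic
mean of those medians over the fixed 10–18 h window (6 h after onset),
computed at fluorescence cadence for biosensors and phase cadence for
cell size, and normalized to the excess control of the same experiment
and window.

## The synthetic-data generator

The generator stands in for segmented microscopy data; it is the
package's account of what the analysis assumes the data look like.

**Growth.**  Cells grow exponentially in area at a condition-level rate:
$\mu_\text{exc}$ before onset, $\mu_\text{ini} = r(f)\,\mu_\text{ad}$
during the adaptation window of length $t_\text{ad}(f)$, and the adapted
rate $\mu_\text{ad} = d_\mu(f)\,\mu_\text{exc}$ afterwards.  A cell
divides when its area reaches the division threshold, splitting 35% of
its area into the bud; divisions conserve area, so the *total* colony
area is exactly piecewise-exponential with breakpoints at onset and
onset + $t_\text{ad}(f)$ — the construction the adaptation estimator is
validated against.  A lognormal size-control jitter (CV 8%) on the
per-cell division threshold, redrawn at each division, desynchronizes
lineages: without it a single-seed colony divides in lockstep and the
population size median oscillates.  The jitter cannot affect any growth
statistic, because divisions conserve area.  No cell-cycle machinery is
modelled; the measured quantities are population aggregates.

**Calibration anchors.**  Dose–response maps are Hyman-filtered
monotone cubics through the anchors: all strains keep 50% of the
excess-control $\mu_\max$ at $f = 0.1$; CEN.PK113-7D and PE2 hold 90% of
the maximal ATP readout at constant limitation, Ethanol Red 70%; the
GlyRNA readout rises 40% from constant excess to constant limitation for
every strain; Ethanol Red's median size falls to 70% at the shortest
excess phases while the other strains plateau near 90%.  Between
anchors the shape is our choice (shape-preserving interpolation, no
overshoot).  Adaptation durations decrease with $f$ within 2–3.5 h,
PE2 slowest at long limitation; the Ethanol Red 9 s/21 s condition is
anchored at exactly 3.1 h with $\mu_\text{ini}/\mu_\text{ad} = 0.5$
(a 100% rate increase at the end of adaptation).

Absolute growth rates are not published for these conditions, so the
defaults use $\mu_\text{exc}$ = 0.20 (Ethanol Red) > 0.185
(CEN.PK113-7D) > 0.17 (PE2) h⁻¹ — the strains' growth ranking — with
constant-limitation rates a quarter of that.  These magnitudes keep
default colonies below the chamber-capacity truncation threshold for
the full 18 h, which the generator's design requires (overflowing
chambers are truncated with a warning, not modelled as washout).  All
acceptance-level quantities are normalized, so absolute rates cancel.

**Sensors and sizes.**  Channel grays are drawn so the QUEEN and GlyRNA
ratios have condition medians equal to the calibrated maps (the ratio of
two unit-median lognormals has median 1, so medians are exact), with
multiplicative lognormal noise of CV 5% per channel; cell areas carry 4%
measurement noise.  Sensor targets switch from the excess level to the
condition level at onset; the 10–18 h statistics window makes the switch
kinetics irrelevant.  The division threshold relaxes to the condition's
size factor linearly during the last 10% of the adaptation window — size
adapts only as growth approaches $\mu_\max$ — and the population median
tracks the threshold because the stationary size distribution of a
threshold-division process is scale- and rate-invariant.  Under the
constant-limitation control the threshold is *raised* (default ×1.12):
cells enlarge under constant limitation even though dynamic short-excess
conditions shrink them.  The realized median ratio also reflects the
slow cycle's age structure and comes out above the raw multiplier
(≈1.3); only its direction (> 1) is anchored.

Ethanol Red carries two heritable ATP subpopulations (levels ×0.75 and
×7/6 around the dose–response mean, 60% high; labels inherited at
division), PE2 a 3% heritable fraction of high-GlyRNA outliers.  The
documented non-monotonic dip of Ethanol Red's ATP below its
constant-limitation level at very short excess is *not* modelled: the
parameter contract keeps every dose–response monotone, and no reported
quantity depends on the dip.

**Randomness.**  One master seed; each chamber derives its own stream,
so chamber $k$'s cells are identical whether 2 or 200 chambers are
simulated.  Identical configuration and seed give byte-identical
tables.

**What the generator does not emulate.**  Images and segmentation
errors, lineage tracking (cell ids are fresh each frame, as in per-frame
segmentation output), mechanistic metabolism (storage carbohydrates,
transporter remodelling), density effects inside a chamber, and
non-stationarity of sensor levels within the statistics window.  Tests
passing on synthetic data therefore validate the *estimators and their
contracts*, not biological claims about real colonies.

## Numerical choices and degenerate inputs

* Log-linear fits need ≥ 3 frames; fewer is an error, as is a sliding
  scan with no complete window.  Constant series get slope 0 and, with
  zero residual variance, $R^2 = 1$.
* Sliding-window ties go to the earliest window; equal slopes within
  $10^{-9}$ h⁻¹ fail the adaptation gate rather than dividing by ~0.
* Flat chamber traces return definition 0 with undefined durations; a
  trace must span ≥ 3 periods for pulse metrics.
* The first-order chamber filter integrates exactly (exponential
  updates between phase boundaries) from the closed-form periodic
  steady state; there is no ODE-solver tolerance to tune.
* Chamber overflow truncates that chamber's records at the offending
  frame; pooled statistics simply lose those rows.
* Empty statistic windows, metric mismatches in normalization,
  non-positive controls and conflicting strain labels are errors, not
  silent results.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the generator at desk
scale, chosen as what a single chip experiment plausibly yields: 20
chambers per condition for dose–response quantities, 5 replicate seeds
for the growth endpoint, 3 replicate sweeps of 15 conditions for the
adaptation endpoint, 200 seeded 15-chamber colonies for
parameter-recovery properties, and 5-chamber noise-free colonies for
exact constructions.  The parameter-recovery tolerance (10% median
error) needs the 1 h initial-rate window to contain enough cells; very
small colonies (≤ 3 chambers) do not reach it at the default
measurement noise, which is an estimator-variance statement, not a
defect.

## Known limitations

The adaptation-time estimator is unstable where adaptation is nearly
absent ($\mu_\text{ini}/\mu_\max \to 0.9$); the gate removes most but
not all of this region, and single-replicate maxima over many conditions
remain positively biased.  The chip model is phenomenological; it
reproduces shift, distortion and smoothing but carries no hydrodynamic
meaning, and the ±2 s-per-step duration transfer outside the immediate
neighbours of the central array is an extrapolation.  The Monod $R^2$
values obtainable here characterize the calibrated synthetic
dose–response, not any measured strain.
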