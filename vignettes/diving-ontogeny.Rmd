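---
title: "Dive classification and diving ontogeny from time-depth records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dive classification and diving ontogeny from time-depth records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diveontogeny)
```

## The problem

Juvenile elephant seals leave their natal colony weeks after weaning and
spend months diving continuously on their first migration. An archival
time-depth recorder (TDR) glued to the animal samples pressure-derived depth
every few seconds and returns, if the animal survives and the tag is
recovered, a depth series of millions of samples. Three scientific
quantities have to be distilled from that series:

1. **What the animal was doing on each dive.** Dives fall into four
   behavioural types: *active-bottom* dives with many vertical inflections
   ("wiggles", putative prey pursuit), *drift* dives in which the animal
   stops swimming and passively floats or sinks, *benthic* dives that track
   the seafloor with a flat, square-cornered bottom, and residual V-shaped
   *transit* dives.
2. **Buoyancy, via drift dives.** A drifting seal moves vertically at its
   terminal drift rate, which is set by its body density. Lipid is lighter
   than seawater, so the drift rate is a longitudinal, non-invasive proxy of
   body condition: positive (floating) when fat, negative (sinking) when
   lean, with *neutral buoyancy* crossings marking phase changes of the
   migration.
3. **Development curves.** Daily 95th percentiles of dive depth and
   duration, and daily median drift rates, against day since departure.

This package implements the whole chain — zero-offset correction, dive
detection, phase segmentation, bottom metrics, the three rule-based
classifiers with their precedence, solar day/night partitioning, daily
summaries, and the cohort statistics — together with a synthetic-trip
generator whose ground truth makes every stage testable without field data.

## Processing model

### Zero-offset correction (ZOC)

Pressure transducers drift, so raw "surface" readings wander away from 0 m.
`zero_offset_correct()` estimates the offset in 6 h blocks as the 2nd
percentile of samples shallower than a 15 m guard depth, interpolates the
block estimates linearly in time, subtracts them and clips corrected depths
below at −2 m. Because quantiles are shift-equivariant, re-correcting a
record after adding any constant offset reproduces the same corrected
record; this invariance is tested directly. Two numerical caveats are worth
stating. First, with Gaussian depth noise of standard deviation σ the 2nd
percentile of true-zero surface readings sits ≈ 2.05 σ *below* zero, so the
corrected surface is biased high by that amount; the bias is common to all
windows and cancels in every between-record comparison, and it vanishes on
noise-free data, which is where the generator's accuracy checks are run.
Second, a block with no near-surface samples (an animal that never
surfaced shallower than the guard within 6 h) inherits the neighbouring
blocks' interpolated estimate, with a warning.

### Dive detection and segmentation

A dive is a maximal excursion below a 2 m surface threshold whose maximum
depth reaches 10 m and whose surface-to-surface duration reaches 30 s; the
alternative 15 m / 60 s "complete dive" criterion of satellite-relay (DSA)
tags is available as `dive_params(preset = "dsa_complete_dive")`. Records
sampled faster than 4 s are decimated (samples dropped, never averaged) to
4 s first, preserving instantaneous depths. The bottom phase is the span
from the first to the last sample at ≥ 80% of the dive's maximum depth —
the standard TDR convention. Note that this span includes the tail of the
descent and ascent ramps (0.2 × depth at transit speed), which matters when
interpreting the bottom range `R`: a perfectly flat benthic shelf still
reports `R` ≈ 0.2 × depth under the default fraction. Dives with fewer than
8 samples, or monotone artefactual records, are flagged.

### Bottom metrics and the intensity index

Over the bottom span the package measures `W` (wiggles: local depth minima
whose vertical swing is at least 2 m on both sides, counted by hysteresis so
that sub-threshold noise adds nothing), `V` (total vertical metres
travelled), `R` (depth range) and `T` (bottom duration). The activity score
is

$$I = \frac{W\,V}{R}\Bigl(1 + \frac{V}{T}\Bigr),$$

zero by definition when `W = 0` or `R = 0`, and a dive is *active-bottom*
when `I > 35` (strict). The formula is isolated in `intensity_index()` so
an alternative algebraic reading can be swapped in one place if exact
replication against other software is needed.

### Drift and benthic detectors

Vertical speed is the first difference of depth with the buoyancy sign
convention, `w = −Δdepth/Δt` (positive = upward), so a positively buoyant
drifting animal has positive drift rate. For each dive a Gaussian kernel
density of all within-dive speeds is evaluated on a fixed grid from −2.5 to
2.5 m/s in 0.005 m/s steps. If the global peak exceeds a density of 1, a
large fraction of the dive happened at one vertical speed: the dive is a
*drift* dive and the peak location is its drift rate.

The *benthic* test runs the same density on bottom-phase speeds only and
requires the peak within ±0.08 m/s with height above 1.5 (a consistent,
nearly flat bottom), **and** a square corner: straight lines are fitted by
least squares to depth-versus-time over the descent span and the bottom
span, and the observed depth at the lines' intersection time must lie
within 15 m (a vertical distance — the only unit consistent with a depth
tolerance) of the intersection. Near-parallel fits (slope difference below
10⁻⁶ m/s) fail the corner test. The conjunction is the default; a
disjunction switch exists (`benthic_rule = "disjunction"`) because the
source description of the two benthic checks can be read either way, and
the bottom-phase "slope close to zero" condition is treated as subsumed by
the ±0.08 m/s peak-location window rather than as a third numeric test.

Labels are assigned with the precedence **benthic > drift > active-bottom >
transit**. The benthic-over-drift override is essential: a flat benthic
bottom is itself a long constant-speed (zero) segment and routinely clears
the drift density threshold. The lower precedence of active-bottom is the
conservative completion: wiggle-rich bottoms spread their speed mass and
essentially never produce a dominant density peak. Exactly one label per
dive; a drift rate is attached only to drift dives.

### Bandwidth: the one calibration that matters

The density-height thresholds (1 and 1.5) are meaningless without a
bandwidth convention, and this is the package's most consequential
numerical choice. A data-driven rule (Silverman's) computes the bandwidth
from each dive's own speed sample: on the trimodal within-dive sample of a
textbook drift dive (60% of samples at −0.3 m/s, the rest at descent/ascent
speeds) it widens to ≈ 0.29 m/s and smears the drift mode to a peak height
of ≈ 0.93 — *below* the drift threshold — while on other dives it shrinks
and inflates peaks. The same dive then crosses the threshold or not
depending on a quantity the threshold knows nothing about. The default is
therefore a **fixed bandwidth of 0.1 m/s**: with it, a dive drifting for a
fraction *f* of its samples peaks near *f* · 3.99 noise-free (so the
threshold of 1 reads "at least ~25% of the dive at one speed", or ~50% under
0.5 m depth noise), and the benthic threshold of 1.5 reads analogously.
Silverman's rule remains available (`kde_bandwidth = NULL`), the bandwidth
floor for degenerate constant samples is 0.01 m/s, and the bandwidth used
is logged per dive in the `kde_bw` output column. Dives with fewer than 10
speed samples get a no-peak sentinel and can never be called drift dives.

### Daily summaries, crossings, day/night

Days are binned from the trip start in UTC (`floor((t − t₀)/86400)`), not
local midnight — reproducible without timezone lookups, and matching the
day-since-departure axis of development curves. Per day: the median drift
rate over that day's drift dives (missing, never zero, on days without
drift dives), the 95th percentiles of maximum depth and duration (linear
interpolation between order statistics, `quantile` type 7), and counts per
type and per day/night stratum. Neutral-buoyancy crossings are the sign
changes of the 7-day running median of the daily drift-rate series,
linearly interpolated to fractional days between valued days.

Day/night is decided at each dive's **start time** (the source convention
is not stated; the start is the only instant every dive has). The animal's
position is interpolated along the great circle between the bracketing
track fixes (antimeridian-safe; a 3 m/s speed cap validates the track), and
the dive is "day" when the solar elevation there exceeds −0.833° — exactly
the NOAA sunrise/sunset zenith of 90.833°, so the test is equivalent to
lying between that date's sunrise and sunset while polar day and night fall
out naturally. `solar_times()` implements the NOAA low-order Fourier
equations (fractional year, equation of time, declination, hour angle); its
unit tests pin it within ±5 minutes of values computed beforehand with an
independent implementation of the higher-order Meeus equations. State-space
track re-estimation is deliberately out of scope: positions come from
documented great-circle interpolation, keeping the 3 m/s cap as a
validation rule only.

### Cohort statistics

`weighted_proportions()` computes each individual's dive-type proportions
and averages them across animals weighted by each animal's dive count.
`two_sample_z_prop()` is the pooled two-sample z-test for proportions
without continuity correction. `mann_whitney_u()` reports the U statistic
for the first sample from midranks; its p-value comes from exact
enumeration of the null distribution whenever `n1·n2 ≤ 400` and the data
are tie-free, and otherwise from the normal approximation with
tie-corrected variance and a continuity correction. The exact/asymptotic
switch matters: the normal approximation's two-sided p can deviate from
enumeration by > 0.1 at the smallest sample sizes, so the exact path is
used everywhere enumeration is cheap. Pooling dives across a handful of
animals treats dives as independent (pseudo-replication); the
per-individual table is returned alongside so the reader can see how much
each animal drives a pooled test.

## The synthetic-trip generator

`generate_trip()` builds a labelled trip from per-dive archetype profiles:
piecewise-linear descent/bottom/ascent plus sinusoidal bottom wiggles — the
simplest family that realizes all four types with closed-form truth.
Defaults emulate the study system: 4 s sampling; a type mix of 44.7%
transit, 29.5% active-bottom, 16.6% benthic, 9.1% drift; target depths
rising from ~80 to ~400 m and durations from ~5.5 to ~20 min over 150 days;
surface intervals of 120 ± 30 s (floored at 40 s; surface behaviour is not
described in the source, so a jittered fixed mean is used); and a drift-rate
trajectory that starts at +0.20 m/s, crosses neutral buoyancy at day 10,
declines to −0.35 m/s by day 50, recovers through the second crossing at
day 125 at 0.01 m/s per day and slows after reaching ≈ +0.13 m/s. The
slope kinks are deliberately placed *away* from zero: the classifier cannot
call a dive "drift" when its rate is within ±0.08 m/s (such dives pass the
benthic flat-bottom test and the override wins), so days near a crossing
are censored from the drift-rate series, and a kink at zero would make that
censored window asymmetric and bias the recovered crossing day.

Realism choices that matter to the detectors, and are therefore part of the
emulation rather than cosmetics:

* **Leg undulation.** Real descent/ascent legs undulate; a mathematically
  linear leg has *constant* vertical speed and would itself register as
  "drifting". Legs therefore carry a zero-mean triangular speed modulation
  (amplitude 0.35 × leg speed, ~90 s period, whole periods per leg so dive
  endpoints and maximum depth are preserved), which makes leg speeds
  near-uniformly spread, as in real profiles.
* **Wiggle geometry.** Wiggle amplitude scales with the bottom zone (10–17%
  of maximum depth) and wiggle count is drawn so the peak wiggle speed
  stays in 0.8–1.8 m/s; small-amplitude wiggles on a deep dive would
  otherwise leave the intensity index hovering at its threshold because the
  80% bottom span dilutes `R` with ramp metres.
* **Drift fraction** is drawn in \[0.5, 0.75\] — drift dives are
  majority-drift by definition — and the drift segment is exactly linear at
  the signed rate.
* **Sensor artefacts.** Gaussian depth noise (default 0.3 m, the resolution
  scale of archival tags) and an optional offset: a constant plus a slow
  random walk (default step 0.001 m per 4 s sample ≈ 0.3 m/day, the scale
  of real transducer drift, clipped to ±5 m).
* **Track.** Hourly fixes stepping along slowly varying headings at ≤ the
  3 m/s cap, from the Año Nuevo colony by default.

Everything is bit-reproducible under the configuration seed, and the
caller's RNG state is restored afterwards.

### What passing tests do and do not show

The generator's dives are *separable by construction*: every truth dive is
detectable (no incomplete surfacings), noise is Gaussian and stationary,
offsets are smooth, and each dive realizes exactly one archetype. Real
records contain hybrid dives, incomplete surfacing between dives, bouts,
haul-outs, light-dependent behaviour and tag gaps, none of which are
emulated. Recovery rates on synthetic trips therefore validate the
*implementation* of the classification chain — thresholds applied as
specified, invariances, precedence, numerical stability — not the
field-data accuracy of the classification rules themselves. One honest
consequence visible in the synthetic results: drift dives whose true rate
lies within ±0.08 m/s of zero are systematically labelled benthic by the
precedence rule, so label accuracy is bounded by the fraction of drift
dives near neutral buoyancy, and daily drift-rate series are censored for a
window of days around each crossing. This is a property of the method, not
of the generator.

## Problem sizes and defaults used in verification

The shipped tests and the acceptance script verify at these scales, chosen
as the smallest that exercise every mechanism: full-trip label recovery on
150-day trips with 4–10 dives per day (600–1,500 dives; ≥ 95% label
accuracy noise-free, ≥ 85% at σ = 0.5 m); drift-rate recovery |estimate −
truth| ≤ 0.05 m/s for ≥ 90% of detected drift dives with daily-median RMSE
≤ 0.05 m/s and both crossings within ±3 days; offset invariance (exact for
constant offsets, ≥ 99% label agreement under the random walk); 10,000-
replicate null calibration of both tests (empirical size 0.05 ± 0.01 at
n = 30); and the solar oracle within ±5 minutes. Unit tests run on 4-day
trips of ~48 dives.

## Known limitations

* The intensity-index algebra follows one reading of an ambiguously typeset
  formula; the function boundary makes the alternative swappable.
* The 2nd-percentile ZOC estimator carries a noise-dependent surface bias
  (≈ 2 σ); comparisons are unaffected but absolute corrected depths are
  biased shallow by up to ~1 m at realistic noise.
* Exact Mann–Whitney p-values are not available under ties (midrank
  asymptotics are used); no multiple-testing adjustment is applied anywhere.
* Day/night at extreme latitudes relies on the low-order NOAA equations
  (±2 min typical, worse within a few degrees of the poles).
* GAMM-based trend fitting and state-space track models are intentionally
  out of scope; daily aggregates plus running medians stand in for smooth
  development curves.
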