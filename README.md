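# diveontogeny

Processing and behavioural classification of time-depth recorder (TDR)
records from diving marine mammals, built around the question of how diving
develops in juvenile elephant seals on their first migration. The package
takes a raw depth series (plus an optional sparse location track) through
zero-offset correction, dive detection, phase segmentation, rule-based
dive-type classification, drift-rate (buoyancy) estimation, solar day/night
partitioning, daily ontogeny summaries and cohort statistics — and ships a
synthetic-trip generator with ground-truth labels so the whole chain is
verifiable end to end.

## The method in brief

A **dive** is a surface-to-surface excursion reaching ≥ 10 m for ≥ 30 s
(15 m / 60 s preset for satellite-relay tags), detected after a sliding
2nd-percentile zero-offset correction. The **bottom phase** is the span at
≥ 80% of maximum depth, over which four metrics are taken: wiggle count
*W*, vertical distance *V* (m), depth range *R* (m) and duration *T* (s).
Each dive then gets exactly one label:

* **active-bottom** — intensity index
  *I* = (*W·V*/*R*)(1 + *V*/*T*) > 35: many wiggles over the bottom phase,
  putative foraging;
* **drift** — the Gaussian kernel density (fixed 0.1 m/s bandwidth, grid
  −2.5…2.5 m/s) of within-dive vertical speed *w* = −Δdepth/Δt has a peak
  higher than 1: much of the dive at one vertical speed. The peak location
  is the **drift rate**, positive = floating = lipid-rich;
* **benthic** — bottom-phase speed density peaks within ±0.08 m/s at height
  > 1.5 *and* the descent/bottom least-squares lines intersect within 15 m
  of the observed trajectory (square corner). Benthic overrides drift:
  flat-bottomed dives routinely pass the drift test;
* **transit** — everything else.

Daily summaries give the median drift rate over the day's drift dives, the
95th percentiles of depth and duration, and counts per type and day/night
(NOAA solar equations at the great-circle-interpolated position). Sign
changes of the 7-day running median of daily drift rate are the
**neutral-buoyancy crossings**. Cohort statistics: dive-count-weighted type
proportions, the pooled two-sample z-test for proportions (no continuity
correction), and the Mann–Whitney U test (exact enumeration when
n₁·n₂ ≤ 400 and tie-free, tie-corrected normal approximation otherwise).

## Worked example

```r
library(diveontogeny)

cfg <- trip_config(n_days = 20, dives_per_day = 20, noise_sd = 0.3, seed = 42)
sim <- generate_trip(cfg)
sim
#> <sim_trip> 20 days, 400 dives (active_bottom=112, benthic=62, drift=33,
#>            transit=193), 432000 samples at 4s

res <- run_pipeline(sim$series, sim$track)
res
#> <dive_pipeline> id=sim01  400 dives (active_bottom=112, drift=19,
#>                 benthic=76, transit=193)  20 days

mt <- match_truth(sim$truth, res$dives)
mean(res$dives$dive_type[mt] == sim$truth$dive_type)
#> [1] 0.965

head(res$daily[, c("day", "n_dives", "median_drift_rate", "p95_depth")], 3)
#>   day n_dives median_drift_rate p95_depth
#> 1   0      20              0.20  101.6683
#> 2   1      20              0.16  114.2076
#> 3   2      20              0.16  107.1900

buoyancy_crossings(res$daily)
#> [1] 10.6
```

Reading the output: all 400 generated dives are detected and classified.
The trip departs positively buoyant (drift rate +0.20 m/s on day 0, the
animal floats) and crosses neutral buoyancy on day ~10.6, within a day of
the generator's true crossing at day 10. Label accuracy is 96.5%; the
truth table shows where the misses live — 14 of the 33 drift dives were
labelled benthic because their true drift rate fell within ±0.08 m/s of
neutral, where the method's own precedence rule cannot distinguish passive
drifting from a flat benthic bottom. The z-test used for day/night
contrasts prints as a standard `htest`:

```r
two_sample_z_prop(60, 100, 50, 100)
#>  Two-sample z-test for proportions (no continuity correction)
#> z = 1.4213, p-value = 0.1552
```

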