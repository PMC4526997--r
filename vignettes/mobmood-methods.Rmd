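---
title: "Behavioral sensing features for depressive-symptom severity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral sensing features for depressive-symptom severity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobmood)
```

## The problem

Depressive-symptom severity is usually measured by self-report instruments
such as the PHQ-9 (0–27; a score of 5 or more indicates at least mild
symptoms). Passive smartphone sensing offers a complementary signal: people
with more severe symptoms tend to move between fewer places, keep less
regular daily schedules, stay home more, and use their phones more. `mobmood`
implements a complete pipeline from raw GPS and screen-state logs to
behavioral features, association statistics, and severity models, together
with a synthetic-cohort generator that makes every stage testable without
access to sensitive raw sensor data.

## Preprocessing

**Stationary vs transition labeling.** The movement speed at each GPS sample
is the backward time-derivative of position: the haversine distance (Earth
radius 6371 km) from the previous sample divided by the elapsed time.
Samples with speed strictly below 1 km/h are *stationary*; the rest are
*transition*. The first sample inherits the second's speed. Because raw logs
have outages, no speed is computed across a gap longer than `max_gap_s`
(default 900 s, three nominal 5-minute sampling periods); samples following
such a gap are labeled `unknown` and excluded from all counts. The strict
`< 1 km/h` convention and the gap rule are our choices where the procedure
is otherwise underdetermined; both are exposed in `preprocess_config()`.

**Adaptive K-means.** Significant places are recovered by clustering only the
stationary samples: K-means is run for K = 1, 2, ... and the first K whose
farthest sample-to-own-center haversine distance falls below 500 m is kept.
Base R's `stats::kmeans` with 10 random restarts under a fixed seed stands in
for k-means++ initialization; results are deterministic given the seed. The
search is capped at `k_max` (default 50) as a safety valve; the returned
model records whether the radius bound was actually met. Cluster occupancy
\(p_i\) is the fraction of stationary *samples* per cluster — a proxy for
time share that is exact under uniform sampling; an elapsed-time weighting
would be a defensible alternative but is not implemented.

**Home identification.** Among the three most-visited clusters, home is the
one most visited between midnight and 6 a.m. participant-local time (local
time = UTC + a fixed per-participant offset; no DST handling). Ties break by
overall visit count, then lowest index. If the trace has no night samples at
all, the most-visited cluster is used and flagged. The heuristic assumes no
night-shift work.

**Screen sessions.** Each `on` event is paired with the next `off`
(consecutive `on`s collapse to the first; a trailing unpaired `on` is
dropped). Sessions shorter than 30 s are discarded as notification-driven
screen wakes; a session of exactly 30 s is kept.

## The ten features

| feature | definition |
|---|---|
| location variance | \(\ln(\sigma^2_{lat} + \sigma^2_{lon})\), population variances in degrees² over stationary samples |
| entropy | \(-\sum_i p_i \ln p_i\) over cluster occupancy |
| normalized entropy | entropy / \(\ln N\); 0 when N = 1 |
| home stay | fraction of stationary samples in the home cluster |
| circadian movement | \(\ln(E_{lat} + E_{lon})\), E = mean Lomb–Scargle power over the 23.5–24.5 h period band |
| transition time | transition samples / (stationary + transition samples) |
| total distance | summed haversine legs (km); legs across >900 s gaps contribute 0 |
| number of clusters | the adaptive K |
| usage frequency | screen sessions per day |
| usage duration | screen-on seconds per day |

All logarithms are natural: the entropy worked examples
(`cluster_entropy(c(0.8, 0.2))` ≈ 0.500, `cluster_entropy(c(0.5, 0.5))` ≈
0.693) fix the base. Location variance is computed in degrees² because the
definition applies the variance directly to the coordinates; the unit choice
shifts the log-variance by a constant and leaves every correlation
unchanged.

**Circadian movement details.** Latitude and longitude are mean-centered
(otherwise the DC offset dominates the low-frequency end) and analyzed
separately with the classic unnormalized Lomb–Scargle periodogram, which
handles the irregular sampling of real GPS logs. The frequency grid runs
from 1/span to 1/(2 × median sampling interval) with oversampling factor 5;
the band energy E is the *mean* power over the grid bins whose periods lie
in [23.5 h, 24.5 h]. Using the mean rather than the sum makes E independent
of the oversampling factor; the two choices differ by a constant log-offset
per fixed grid and do not affect correlations. Only the band bins are
evaluated (the rest of the grid does not enter the feature), which keeps the
per-participant cost trivial; `lomb_scargle_psd()` exposes the full
periodogram for diagnostics. Traces shorter than 24 h, or with zero band
energy, give `NA`.

## Data-sufficiency filter

A stream is analyzed only when it covers more than half the study period —
strictly more. Location coverage is the fraction of nominal 5-minute bins
containing at least one sample; usage coverage is the fraction of calendar
days with at least one screen event. "Time" in the coverage rule could also
be read as waking hours; the binned reading matches the sampling design and
is one of several defensible operationalizations. Location and usage
eligibility are assessed independently, since the two analyses can have
different participant subsets.

## Association statistics

Per-feature Pearson correlations with the PHQ-9 score (p from the t
transform with n − 2 df, pairwise-complete), a group comparison between
participants at or above the cutoff of 5 and those below using Welch's
unequal-variance t-test (the pooled-variance variant is available via
`var_equal = TRUE`), and the pairwise feature–feature correlation matrix.
No multiple-comparison correction is applied: the association table is
descriptive screening, and the package reports raw p-values so users can
apply their own correction.

## Severity models

The score model is linear, `score = a0 + Σ ai Fi`, fit by least squares; the
classifier is logistic with the 0.5 probability rule, positive class =
"has symptoms" (PHQ-9 ≥ 5). With more than two features the coefficients are
elastic-net regularized:

\[ \tfrac12\,\mathrm{RSS} \;+\; \lambda_1 \lVert \beta \rVert_1 \;+\;
   \tfrac{\lambda_2}{2} \lVert \beta \rVert_2^2 \]

with the intercept unpenalized (standard practice) and the L2 term entering
as the squared norm, the form under which the elastic net was introduced and
analyzed. The solver is cyclic coordinate descent, written in this package;
the logistic fit is penalized IRLS whose weighted least-squares steps reuse
the same coordinate descent (or an exact weighted solve when \(\lambda_1 =
0\)). With no penalty the linear fit reduces to exact QR least squares, and
a rank-deficient design raises an error advising regularization. Features
are standardized to zero mean/unit SD inside each training fit; returned
coefficients are on the original scale. λ grids default to 10 log-spaced
points over \([10^{-4}, 10^2]\) per penalty, tuned by 5-fold cross-validation
on the training entries only; inner-CV candidate fits run at a relaxed
tolerance since they only rank candidates, and the selected model is refit
tightly.

**Evaluation protocol.** `bootstrap_lopo_evaluate()` draws B bootstrap
resamples of participants (B = 1000 in the original protocol; tests and
examples use smaller B), runs leave-one-entry-out cross-validation within
each resample, pools the held-out predictions, and reports means and SDs
across resamples of accuracy, sensitivity, specificity, and NRMSD (RMS error
divided by the observed score range of the input cohort). Resampling with
replacement means a held-out entry's participant can also appear in
training; the protocol is implemented literally at the entry level, and the
report carries the average duplicate-leak rate so the resulting optimism can
be quantified. `unique_participants = TRUE` switches to unit-level hold-out.
Resamples lacking two entries of either class (or with zero score range) are
redrawn and counted. With B = 1 and the identity resample the procedure
reduces exactly to plain leave-one-participant-out.

## The synthetic cohort

`generate_cohort()` draws a latent severity \(u \sim U(0,1)\) per
participant, shifts baseline behavioral parameters along per-parameter
slopes, and sets `phq9 = round(clip(score_max · u + ε))` with Gaussian ε.
Each simulated participant lives on a local planar patch: a home anchor plus
`n_anchors − 1` significant places at mutual separation above 1 km (twice
the clustering radius), so each visited anchor maps to one recoverable
cluster; impossible separation requests raise a generation error. Days are
*canonical* with probability `regularity` (fixed departure/return around a
13:30 midpoint, fixed destinations) or *irregular* (shuffled times and
destinations); time away from home is set by `home_stay_frac`. Transitions
are constant-speed (25 km/h) interpolated runs, so the speed labeling sees
genuine transition samples. Positions get Gaussian GPS jitter (default SD
15 m, a realistic phone-GPS figure chosen so that jitter between consecutive
5-minute samples stays well below the 1 km/h threshold); samples are dropped
uniformly at random to the `coverage` fraction; screen sessions follow a
Poisson daily count with exponential durations (mean 70 s, so a sizeable
share falls under the 30 s filter).

Default study conditions mirror a two-week study at 5-minute sampling with
28 participants. The default link plants the associations the features are
designed to detect: rising severity increases home stay (+0.35 over the unit
severity range) and phone usage (+20 sessions/day, +90 s mean duration) and
decreases schedule regularity (−0.65) and spatial spread (−3.5 km). Under
the full-scale score map `round(27u)` only ~19% of participants fall below
the cutoff of 5; the package therefore also provides the balanced
`score_range = c(0, 10)`, which puts the cutoff at the latent median and
yields the roughly half-and-half split typical of small clinical cohorts.
The full-scale range remains the `severity_link()` default; cohorts intended
for classification work use the balanced range explicitly.

**What the generator does and does not emulate.** It reproduces the
statistical structure the features measure — cluster-concentrated stationary
time with a dominant home cluster, circadian-regular transitions, GPS
jitter, missingness (including participants below the 50% coverage bar via
`low_coverage_frac`), and screen sessions of varying count and duration. It
does not attempt demographically realistic mobility: no road networks,
no weekday/weekend structure, no correlated outages, no night-shift
schedules. Passing tests therefore demonstrate that the pipeline recovers
planted effects of realistic magnitude under the stated sampling design —
not that real cohorts will show effects of that size.

## Numerical choices and degenerate inputs

- Zero-variance location input → `NA` with a warning (log of 0 is avoided
  throughout; zero band energy likewise gives `NA`).
- Duplicate log timestamps keep the first row; malformed rows are counted
  and reported, and a file with no valid rows is an error.
- Coordinate descent converges on a max-coefficient-change tolerance of
  1e−11 (5e4 iteration cap); IRLS on relative deviance change 1e−10.
- K-means ties and restarts are fixed by the configured seed; the adaptive
  search is strictly incremental from K = 1.
- Problem sizes in the test suite: cohorts of 28 (protocol checks), 60
  (null-association check), and 50 replicates of n = 100 (sign-recovery
  check); bootstrap checks use B = 50. These sizes give the Monte-Carlo
  margins the assertions need while keeping the default suite fast.
- Null calibration uses a permutation design: a no-link cohort whose PHQ-9
  scores are a seeded balanced permutation (half per side of the cutoff),
  pinning chance accuracy at 50% regardless of how an unconstrained random
  split would have landed.

## Known limitations

- Occupancy weights samples, not elapsed time; the two diverge under heavily
  nonuniform sampling.
- The entry-level bootstrap-LOPO protocol is optimistic in proportion to the
  duplicate-leak rate it reports; unit-level hold-out is available but is
  not the default, to keep the literal protocol.
- The home heuristic fails for night-shift participants by construction.
- A fixed tz offset ignores DST transitions (at most one hour of night-window
  misalignment for up to two days per year).
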