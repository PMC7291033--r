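---
title: "Models and methods behind larvatrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind larvatrax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrax)
```

`larvatrax` quantifies larval zebrafish behavior and neuronal calcium
activity from tracked 2-D positions and per-cell fluorescence traces.
This vignette explains the models and procedures, the parameters that
matter and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Arena geometry and zones

All assays happen in a circular arena with the origin at its center and
coordinates in mm. Two partitions of the disc are used:

* **border vs center** — a point is in the border iff its distance from
  the wall, $R - \sqrt{x^2+y^2}$, is at most the border width $w$.
  Default $w = 4$ mm, roughly one body length of a 4 dpf larva; the
  convention in the open-field literature defines the border as a
  body-length-wide annulus, and the exact width is exposed in
  `arena()`/`assay_config()` because tracking setups differ.
* **light vs dark** — the half-plane $x < 0$ is dark by default; the
  measure-zero line $x = 0$ is assigned to light so the partition is
  deterministic.

Tracking jitter routinely places a wall-hugging larva a fraction of a
millimetre outside the nominal wall. `validate_trajectory()` clamps
excursions up to 2 % of the radius back onto the wall and treats anything
larger as corrupt data rather than guessing.

## Locomotor metrics and the preference indices

Per-step speed is the Euclidean step length times the sample rate. From it:

* **movement dichotomy** — a step is "moving" iff its speed is at least
  the movement threshold (default 2 mm/s). Tracking software applies a
  similar start/stop velocity internally but its value is rarely
  reported, so the threshold is explicit, configurable, and written into
  every report.
* **fast movements** — events are *maximal runs* of consecutive steps
  with speed above 20 mm/s. Counting frames instead of runs would make
  the result scale with the camera rate, which is why runs are the
  default and only rule.
* **zone occupancy** — each inter-sample interval is assigned to the zone
  of its *starting* point (a left-closed rule). The rule is simple and
  deterministic; the price is at most a one-sample error in any duration,
  which the occupancy invariant (durations sum to the recording length
  ± one sample) makes explicit.

The thigmotaxis index is the percentage of total time (moving plus
not-moving) spent in the border; the phototaxis index is the same with the
illuminated half. Both are complementary by construction: border and
center indices sum to exactly 100, as do light and dark.

Light-preference classification uses the published cutoffs: index > 70 %
is phototaxis, < 30 % scototaxis. Both printed rules are strict
inequalities, which leaves the boundary values unassigned; `larvatrax`
maps 30 and 70 exactly to *no preference*, the only choice that keeps the
three classes exhaustive without widening either tail class.

Subjects whose total distance over the whole recording is strictly below
10 mm are rejected by `activity_filter()` before any statistics, and every
rejection is logged with the subject id.

Mean velocity per bin is distance divided by *bin duration* by default,
which includes immobile time. Distance divided by time-in-motion is
available via `velocity_mode = "moving_time"` because figure legends in
this literature rarely say which convention they use.

## Visual-motor response and seizure-like episodes

The standard protocol is three 10-min phases: baseline in darkness, a
low-activity phase at 70 % light (light-on suppresses swimming after a
brief startle), and a high-activity phase back in darkness. Phases are
half-open $[start, end)$ intervals; per-phase distance and mean velocity
are computed independently, and phase distances sum exactly to the total.

**Seizure-like episodes** are windows of extreme locomotion: the recording
is partitioned into consecutive non-overlapping 60 s windows anchored at
$t = 0$, and every window whose distance strictly exceeds 200 mm is one
episode with the window distance as its amplitude. Tumbling rather than
sliding windows were chosen because the amplitude is defined as "distance
in one minute" — a sliding window would count a single burst many times.
The episode count is monotonically non-increasing in the threshold, which
the property tests assert.

Two caveats worth knowing:

* A Poisson burst process is undercounted by tumbling windows whenever
  two bursts land in one window (a factor $(1-e^{-\lambda w})/(\lambda w)$)
  and a burst can be split across a window boundary so that neither half
  crosses the threshold. Recovery analyses in the test suite therefore
  use a window matched to the burst duration (6 s windows, 60 mm
  threshold for 2 s bursts at 80 mm/s), where those losses stay below
  ~10 %. The 200 mm / 60 s default is unchanged — it is the published
  criterion and appropriate for minute-scale convulsant episodes.
* The episode definition is purely distance-based. Whirlpool-like
  circling is reported separately by `circling_score()` (net signed
  heading change over moving steps per window, in revolutions) and never
  gates detection, because no numeric circling criterion is published.

`startle_response()` reports the distance traveled in the 5 s after each
light transition; 5 s covers the visible startle transient without
bleeding into the sustained phase response.

## Calcium oscillation analysis

Traces are per-cell fluorescence series sampled at 1 Hz for 5 min, as
produced by single-plane lightsheet imaging of GCaMP-expressing neurons.
Peak detection follows the slope-change principle:

1. smooth with a centered moving average (window 3 samples);
2. take the first difference and mark a candidate peak at every
   $+ \to -$ sign change (plateaus inherit the preceding sign);
3. accept a candidate iff the rise from the smoothed minimum since the
   last accepted peak (the preceding trough) is at least `min_rise`;
   by default `min_rise` is $1.5 \times \mathrm{MAD}$ of the
   first-differenced raw trace, a robust noise scale.

The window and threshold defaults were calibrated on the package's own
simulator at SNR 10 (amplitude 10, noise SD 1, event rate 0.04–0.05 Hz,
300 s): a 3-sample window with $k = 1.5$ recovers ≥ 95 % of true events
within ±3 s with < 7 % false peaks and estimates the event rate to within
15 % on every tested seed. A 5-sample window — a natural first guess —
flattens a transient whose decay constant is only 1.5 s at this frame
rate and misses roughly half the events; $k \ge 2$ over-prunes stacked
transients. Two events closer than ~2 s merge into one sampled rise and
are indistinguishable at 1 Hz in principle; that merging is the dominant
residual bias in frequency estimates.

Oscillation frequency is peak count divided by recording duration (so
frequency × duration = count, exactly), and amplitude is peak minus
preceding trough *on the smoothed trace*; with no detected peak the
frequency is 0 and the amplitude is reported missing, never zero.

Group tables are assembled at the cell level by default, matching how
cell counts are reported in this literature; cells of one animal are not
independent, so per-animal aggregation (mean over cells) is available via
`group_oscillations(..., aggregate_by_animal = TRUE)` and is the
conservative choice for confirmatory claims.

## The statistical harness

The tests mirror standard practice in this assay literature: paired t
within subjects (border vs center, light vs dark), Wilcoxon rank-sum
between genotypes, Kruskal–Wallis across more than two groups followed by
pairwise rank-sum post hocs with Benjamini–Hochberg adjustment, Pearson χ²
on the response-class distribution, ΔΔCt fold changes for qPCR, and
per-gene equal-variance t-tests with a BH FDR column for expression
tables. All p-values are two-sided. Choices worth stating:

* Rank-sum p-values are exact (by enumeration of the null) for combined
  samples up to 12 without ties, otherwise a tie-corrected normal
  approximation without continuity correction. The exact branch is
  verified against a full enumeration oracle for every tie-free input up
  to $n_1+n_2 = 8$.
* χ² uses no continuity correction by default (`correct = TRUE` is
  available); with the published 2×3 response counts this reproduces the
  printed p = 0.2419 to four decimals.
* BH adjustment is order-preserving and monotone but *not* idempotent in
  general — re-adjusting an adjusted vector re-applies the step-up
  penalty — so adjusted p-values are flagged as such in outputs and never
  fed back through the harness.
* Degenerate inputs (zero-variance paired differences, all-identical
  groups, zero table margins, zero-variance genes) raise errors or are
  flagged, never silently produce p-values.

## The synthetic-data generator

`simulate_trajectory()` is a correlated random walk with a two-state
speed process: quiescent larvae are still; bouts start as a Poisson
process (`bout_rate`, default 1 /s), last 0.2 s (a typical burst-swim
duration, kept internal), and draw their speed from a gamma distribution
(mean 4 mm/s, shape 4, capped at five times the mean so the maximum step
speed has a closed-form bound). Heading accumulates Gaussian turns
(`turn_sd`) plus, when `wall_bias > 0`, a pull toward the outward radial
direction — the minimal mechanism that produces thigmotaxis. Per-phase
speed multipliers and a post-transition `startle_boost` emulate
visual-motor modulation, and Poisson-timed seizure bursts override
locomotion with constant fast speed and constant signed angular velocity
(whirlpool-like circling, direction random per burst). Positions reflect
at the wall.

`simulate_calcium_traces()` renders Poisson-timed transients as
difference-of-exponentials kernels (rise 0.2 s, decay 1.5 s, unit peak)
with gamma-distributed amplitudes on a baseline with optional linear
drift and white Gaussian noise, and returns the ground-truth event times
alongside the traces. Amplitudes are arbitrary units by design, since
published amplitudes are AU as well.

Determinism: every simulator takes an explicit seed, restores the global
RNG state on exit, and cohorts derive per-subject seeds from a master
seed by a fixed linear-congruential hash, so reproducibility does not
depend on cohort size or call order.

What the generator deliberately does **not** emulate: body posture and
tail kinematics, multi-larva interaction, wall-following hydrodynamics,
photobleaching or motion artifacts in imaging, and spatially correlated
network activity across cells. Passing recovery tests therefore show that
the analysis chain inverts its own generative assumptions at realistic
noise levels — not that those assumptions exhaust real tracking or
imaging data.

## Problem sizes used in the test suite

Property and recovery tests run on deliberately compact problems so the
suite stays fast while keeping the statistics meaningful: open-field and
seizure recovery cohorts use 20 subjects per group at 5 Hz over 2–5 min
recordings, repeated over 20 independent master seeds (a recovery check
must succeed at p < 0.05 in at least 18 of 20); calcium recovery uses
20–50 cells at 1 Hz over 300 s. The full published protocols (25–30 Hz,
10–30 min, three experimental repeats) are what `assay_config()` defaults
describe and what the pipeline expects for real data.

## Known limitations

* Interval-based zone assignment has a one-sample resolution limit; at
  25 Hz this is 40 ms per transition, negligible for minutes-long assays.
* Frequency estimates at 1 Hz are biased low by event merging (see
  above); raising the imaging rate, not the detector, is the fix.
* Cell-level comparisons pseudo-replicate animals; use per-animal
  aggregation for inference that must generalize across fish.
* The rank-sum exact branch enumerates $\binom{n_1+n_2}{n_1}$ outcomes
  and is capped at combined n = 12 for that reason.
* `de_group_test()` with two samples per group inherits the instability
  of a two-observation variance estimate; it implements the stated
  procedure faithfully, but moderated-variance methods are preferable for
  real expression data.
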