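---
title: "Resolving fishing trips from gappy VMS streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving fishing trips from gappy VMS streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmstrips)
```

## The problem

Vessel monitoring systems (VMS) report a fishing vessel's position on a
mandated cadence — 30 minutes for the Bering Sea pollock fleet — regardless
of what the vessel is doing. Turning that position stream into *trips*
(dock-to-dock excursions with a duration, a distance, and a fishing /
non-fishing label) sounds like a simple point-in-polygon exercise, but real
streams are messy: duplicate records, position glitches implying impossible
speeds, intervals jittered out to 35–60 min, and outright gaps that can
swallow an entire port visit. `vmstrips` implements a full pipeline that is
robust to these defects, validates its duration estimates against at-sea
observer logs, matches trips to landings reports (fish tickets), classifies
trips with decision rules plus a logistic GAM, and quantifies the distance
bias that transmission gaps introduce.

Because real VMS, observer and fish-ticket data are confidential, the
package ships a synthetic-fleet generator with full ground truth. Every
stage of the pipeline is tested against that truth.

## The synthetic fleet

`simulate_fleet()` builds, per vessel, a chain of dock dwells and trips:

* **Fishing trips** (pollock-style `afa_fishing`, or `other_fishing`)
  last 1–4 days (uniform, plus a travel allowance when the start and end
  hubs differ): a transit leg at 8–12 kn out to grounds on the shelf,
  sinuous slow legs at 0.5–5 kn with frequent course changes and
  occasional tow reversals, and a transit home. The slow/fast speed bands
  follow the fleet's observed behavior (maximum speeds ~12 kn; fishing at
  0–5 kn).
* **Transits** are straight constant-speed port-to-port runs.
* **Tenders** transit to an offshore loiter station (placed clear of every
  port buffer) and wander there at under 1.5 kn before running home.

Tracks are generated at 1-min resolution by great-circle dead reckoning
(sphere, R = 6371 km) — finer than any sampling interval, so the truth
path length is effectively exact. Trips chain: each starts where the last
ended, so the continuous track never teleports. Randomness flows from one
seed argument through R's global RNG stream, the conventional reproducibility
mechanism in R simulation code.

`sample_vms()` emits records at the empirical interval mix: by default
8.9% of intervals are jittered uniformly into 35–60 min and 2.1% are long
gaps drawn from {90, 120, 150, 240, 480} min with geometrically decreasing
weights. The gap-length distribution is a modelling choice — no empirical
distribution is available for it — and its 60-min member was deliberately
dropped so the two defect classes (jitter vs gap) remain disjoint and
testable against a binomial oracle. Observer logs and fish tickets are
emitted from truth, with optional clock error, coverage below 1, swapped
ticket dates, and blank ports. Tender periods are also emitted as a
registration calendar, mirroring the processor records a real analysis
would have.

What the generator does *not* emulate: weather and current drift, GPS
measurement noise, within-port shuttling between docks and processors,
floating processors in unexpected locations, or inscription errors beyond
the modes above. Passing tests therefore demonstrate the pipeline's logic
under realistic sampling defects, not its performance on every real-world
contingency.

## Preprocessing

Records are deduplicated per (vessel, timestamp) (first occurrence kept),
then enriched: inter-record great-circle distance (haversine, R = 6371 km,
reported in nautical miles), transmission interval, implied speed, nearest
port and distance, and statistical-area membership (point-in-polygon,
boundary inclusive). Records implying speeds above 14 kn — a conservative
ceiling over the fleet's ~12-kn maximum — are removed by a forward scan
that re-links each record to the last kept one and repeats until clean;
whether such removal should cascade is an open choice, and cascading was
picked because a single glitched fix often corrupts two intervals.
Observer linkage is interval membership with inclusive bounds; overlapping
observer intervals for one vessel are an input error, not data.

## Port status and trip segmentation

A record is **in-port** when it lies within the nearest port's detection
radius *and* the stop is confirmed — by slow speed (default ceiling 2 kn)
or by a dwell of at least 60 min inside the radius. Distance alone cannot
separate "entering port" from "passing a port", so the confirmation applies
to the 10-nmi hub buffers as well as to the tighter (<10 nmi) radii of
small exposed ports. Dwell runs are edge-trimmed: a record still moving at
the head of a run (judged by where the vessel goes next) or the tail
(judged by where it came from) is arrival/departure transit, and the
remaining core must itself average at or below the speed ceiling over its
own path. Declared transit corridors (e.g. between two hub ports) suppress
in-port status for vessels moving through at speed.

Trips are maximal at-sea runs bracketed by the adjacent in-port records.
Gaps up to 240 min are kept interior to a trip — the dominant failure mode
of naive segmentation is gaps longer than 4 h — while longer gaps trigger
port-visit inference: a port splits the run when it lies essentially on
the path between the flanking records (cross-track distance within its
radius plus 2 nmi, along-track position between them) or both flanks sit
within 1.5 radii, and the detour implies at most 14 kn. This deliberately
refuses to split on long gaps in open water, where a reachable port always
exists but a visit is not evidenced. Trips of four or fewer records
(~2 h of spurious threshold crossings) are pruned.

## Durations, distances and the error model

A trip's clock starts at its **first at-sea record**: the leading in-port
record anchors the start port and the path, but not the departure time.
This convention is pinned by the error model's worked example (observer
departure 12:01, records at 12:00 and 12:30: the trip starts at 12:30, a
29-min discrepancy) and makes the start error (up to one interval, early)
and end error (up to one interval, late — trips end at the first in-port
record after the run) symmetric. Hence the duration error bound of
**2 × interval − 2 min** (58 min at the 30-min rate), which the package
applies per trip using the trip's own largest interval, since the error
grows with the gap actually present.

Distances sum the great-circle legs between successive records. At small
ports, the boundary record is linearly extrapolated to the dock along its
adjacent segment's speed (floored at 0.5 kn so a near-stationary segment
cannot add unbounded time — a guard the source procedure leaves
unspecified). The two hub ports sit in large protected bays where the
10-nmi buffer hides substantial in-port travel, so there the measured span
is trimmed to the radius crossing (linear interpolation on the crossing
leg) and replaced by per-port **in-port constants** — mean distance and
duration between dock and threshold, estimated from traversals with
contiguous (≤30 min) records. The registry carries published fallback
constants (Dutch Harbor 10 nmi / 80 min each way; Akutan 13 nmi / 101 min
outbound, 12 nmi / 92 min inbound) for when no traversal qualifies; the
pipeline re-estimates them from the data at hand, which is also what keeps
the synthetic validation honest — the synthetic fleet's true in-port
travel is whatever its vessels actually did.

`compare_with_observer()` pairs trips with observed trips sharing at least
one record, drops observed trips of 200 min or less (below the method's
resolution), discards ambiguous multi-matches, and reports the share of
durations within the error bound, within 5%, their union, Spearman rank
correlation, and the aggregate (summed) duration error.
`bias_correction_regression()` models observed on estimated log-duration
piecewise around 700 min — the trough of the bimodal duration distribution
separating short non-fishing from multi-day fishing trips — and returns
corrected durations with before/after error summaries so the user can
accept or reject the correction; other functional forms can be fitted on
the returned comparisons directly.

## Classification

Features follow fixed record subsets: `avesp`/`sdsp` (mean/SD speed, only
records >10 nmi from port moving >0 kn), `sddif`/`avedif` (SD/mean of
consecutive speed differences among records at fishing speeds, 0–5 kn),
`avgspstat` (mean speed inside designated fishing areas), trip duration,
start/end port region, and pollock season (A: Jan 1–Jun 9, B: Jun 10–Oct
31, N otherwise; configurable). Empty subsets yield NA plus a missingness
flag; NAs are imputed with training medians.

Tier 1 is an ordered rule set (first match wins): ticket-matched trips are
fishing; corridor-only trips, tender-calendar trips, and trips with no
slow records beyond 10 nmi are non-fishing. Tier 2 fits the logistic GAM

```
logit(p(fishing)) = s(ln duration, avesp) + s(sddif) + s(sdsp)
                    + season + start region + end region
```

with an isotropic bivariate smoother for duration × mean speed (longer
trips contain more transit, raising mean speed), thin-plate univariate
smoothers elsewhere, and default penalty selection. Training excludes
trips outside (200, 15000) min and ambiguous observer overlaps; basis
dimensions shrink automatically when a feature has few unique values, and
factor terms drop out when the training data hold one level. The decision
threshold is 0.5, with ties labelled fishing. `avedif`, `avgspstat` and
vessel size are computed as candidate covariates but excluded from the
default model. Tier 3 resolves AFA vs non-AFA fishing: program tickets
decide matched trips; unmatched fishing trips in a month where the vessel
landed no AFA tickets are non-AFA, otherwise the pollock season decides.

## Gap-bias simulation

From trips whose intervals all sit in 25–35 min, the experiment samples
trips with replacement (default 5,000 draws; the pipeline demo uses fewer),
picks a removal position uniformly, and removes k = 1–4 consecutive
records — the block extends backwards from the first removal — creating a
single gap of (k+1) × 30 min. The per-draw percent reduction uses the
over-water path as denominator (in-port constants are gap-invariant).
Straightening can only shorten a polyline, so reductions are nonnegative
and nondecreasing in k per draw; summaries report mean, mean absolute
deviation, quartiles and outliers beyond 1.5 × the upper quartile, plus
the ECDF of each input trip's largest gap. An exhaustive-enumeration
companion (`exhaustive_mean_reduction()`) provides the exact per-trip mean
the Monte Carlo converges to. Note that the *percentage* reduction scales
inversely with total trip length: removing a fixed 150-min window cuts a
roughly fixed number of nautical miles, so multi-day synthetic fishing
trips yield sub-1% mean reductions, and the same local straightening
weighs far more on short trips.

## Numerical and design choices

* Haversine on a 6371-km sphere everywhere; sub-0.5% versus a geodesic at
  subarctic latitudes, and one convention that tests can pin exactly.
* Timestamps are UTC throughout; ticket dates are calendar days, and a
  record "falls within" a ticket window if its UTC date lies in
  [fishing start, landing] inclusive.
* Many-to-one ticket matches resolve by area/window overlap count, then
  end-time proximity to the landing date; one-to-many matches are kept.
* Nearest port wins when two port radii contain a record.
* Degenerate inputs: empty record sets flow through; a single-class label
  vector or an all-constant regressor aborts or falls back to an identity
  correction with a warning rather than fitting nonsense.
* Problem sizes in the test-suite and acceptance runs: shared fixtures of
  ~25 trips, fleet-scale checks at 500–560 trips, 4,000-draw Monte Carlo
  versus exhaustive enumeration; these sizes give stable percentages while
  keeping a full run to a few minutes.

## Known limitations

* Port-specific rule constants (speed ceiling, dwell, corridor polygons)
  are configurable but default to one global pair; a production deployment
  would tune them per port as the source analysis did.
* Gap port-inference requires geometric evidence and will miss port visits
  whose flanking records are both far away and off-path; such cases remain
  merged trips.
* The classifier's accuracy on synthetic fleets benefits from cleanly
  separated behavioral regimes; real fleets mix behaviors within trips.
* The bias regression is one representative of a family of correction
  models; it improved aggregate error on synthetic data but, as with the
  source analysis, trip-level corrections can go either way.
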