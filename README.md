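# vmstrips

Identify, measure and classify fishing-vessel trips from sparse, gappy
vessel monitoring system (VMS) position streams.

Fisheries effort is usually measured as time spent fishing, but whole
trips — from leaving the dock to tying up again — carry the information
needed for fleet dynamics, fisher behavior and cost analyses. Resolving
trips from VMS data is hard precisely where it matters: transponders that
should report every 30 minutes jitter out to 35–60 minutes, fall silent
for hours, and occasionally report impossible positions, so port visits
get missed and naive point-in-polygon segmentation breaks. `vmstrips` is
for analysts working with VMS-style position data (vessel id, timestamp,
lat, lon) alongside port registries, statistical-area polygons, landings
reports (fish tickets) and at-sea observer logs.

The package provides the full pipeline:

* **Preprocessing** — deduplication; derived kinematics (interval,
  distance, speed, nearest port, stat area); iterative removal of records
  implying speeds over 14 kn.
* **Trip segmentation** — in-port detection from distance + speed/dwell
  confirmation, robust to missing fixes; gaps over 4 h are tested for a
  hidden port visit via a geometric + 14-kn feasibility check; trips of
  ≤4 records pruned.
* **Ticket matching** — stat-area × date-window overlap, port backfill
  with the 14-kn quality check, AFA / non-AFA partition with the
  vessel-month rule.
* **Trip metrics** — durations and distances with dock extrapolation and
  hub in-port constants (estimated from contiguous dock-to-threshold
  traversals); the measurement-error bound `2 × interval − 2` min;
  observer comparison; optional piecewise log-linear bias correction with
  a 700-min breakpoint.
* **Classification** — decision rules, then a logistic GAM
  `logit(p(fishing)) = s(ln dur, avesp) + s(sddif) + s(sdsp) + season +
  start + end` (mgcv), threshold 0.5.
* **Gap-bias simulation** — remove 1–4 consecutive records from
  complete-transmission trips (gaps of 60/90/120/150 min) and measure the
  percent reduction in path length, with an exhaustive-enumeration oracle.
* **Synthetic fleet generator** — ground-truthed vessels, tracks at 1-min
  resolution, VMS sampling with the empirical 8.9% / 2.1% interval defect
  mix, observer logs, fish tickets and tender calendars, so everything is
  testable without confidential data.

## Worked example

```r
library(vmstrips)
res <- run_pipeline(pipeline_config(n_vessels = 5, trips_per_vessel = 4,
                                    gapsim_draws = 500, seed = 7))
#> [simulate] fleet: 5 vessels x 4 trips, seed 7
#> [simulate] 20 truth trips, 2278 VMS records
#> [preprocess] 2278 records after dedup + speed filter (0 removed)
#> [segment] 22 raw trips
#> [segment] 21 trips after pruning (1 short trips removed)
#> [tickets] 17 trip-ticket pairs; 0 bad-date tickets excluded
#> [metrics] durations and distances computed (in-port constants: dutch_harbor, akutan)
#> [observer] 19 pairs; 100.0% within error bound; aggregate error 0.85%
#> [classify] labels: afa_fishing=15, nonfishing=4, other_fishing=2

truth_recovery(res$ts, res$fleet$truth)$one_to_one
#> [1] 1
str(res$comparison$summary)
#> List of 7
#>  $ n                  : int 19
#>  $ share_within_bound : num 1
#>  $ share_within_5pct  : num 0.895
#>  $ share_within_either: num 1
#>  $ spearman_rho       : num 0.996
#>  $ aggregate_pct_error: num 0.848
#>  $ mean_abs_pct_error : num 1.28
```

Every ground-truth trip was recovered one-to-one; all 19 estimated
durations fall within their measurement-error bound (58 min at the 30-min
rate, wider where the trip's own intervals are longer); estimated and
observed durations agree to a Spearman ρ of 0.996 with a 0.85% aggregate
error. The season × year × label report is in `res$report`.

The gap experiment is clearest on gap-free streams, where sinuous fishing
trips qualify as complete:

```r
fleet <- simulate_fleet(n_vessels = 12, trips_per_vessel = 5,
                        sampling = sampling_model(jitter_fraction_35_60 = 0,
                                                  long_gap_fraction = 0),
                        seed = 3)
rec <- preprocess_vms(fleet$records, fleet$ports, fleet$areas)
rules <- port_rules(fleet$ports)
rec <- assign_port_status(rec, rules)
ts <- prune_short_trips(segment_trips(rec, rules))
run_bias_experiment(ts, n_draws = 5000, seed = 3)
#> <gap_sim> 5000 draws over 60 complete trips
#>  k_removed gap_min mean_pct mad_pct      q25  median   q75 n_outliers n_draws
#>          1      60    0.118   0.148 6.27e-09 0.00861 0.138        985    5000
#>          2      90    0.286   0.303 2.39e-08 0.10052 0.460        742    5000
#>          3     120    0.476   0.462 6.04e-08 0.26860 0.784        614    5000
#>          4     150    0.688   0.628 1.15e-07 0.49432 1.141        534    5000
```

Longer gaps straighten trajectories more: mean reductions grow with the
number of removed records and are never negative. Percent reductions scale
inversely with total trip length — these multi-day trips dilute the local
straightening; see the vignette for discussion.

A thin command-line wrapper lives at `inst/cli/vmstrips.R`
(`Rscript inst/cli/vmstrips.R run --seed 1 --out out/`).

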