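# Shared synthetic fleets, built once per test run. Sizes are kept modest
# so the whole suite stays fast; the acceptance tests build their own
# larger fleets.

.fleets <- new.env(parent = emptyenv())

# paper-level interval mix (8.9% jitter, 2.1% long gaps)
small_fleet <- function() {
  if (is.null(.fleets$mix)) {
    set.seed(NULL)
    .fleets$mix <- simulate_fleet(n_vessels = 6, trips_per_vessel = 4,
                                  seed = 101)
  }
  .fleets$mix
}

# gap-free, jitter-free stream: every interval exactly 30 min
clean_fleet <- function() {
  if (is.null(.fleets$clean)) {
    .fleets$clean <- simulate_fleet(
      n_vessels = 6, trips_per_vessel = 4,
      sampling = sampling_model(jitter_fraction_35_60 = 0,
                                long_gap_fraction = 0),
      seed = 202)
  }
  .fleets$clean
}

# run a fleet through preprocess + segmentation + pruning + metrics,
# estimating hub in-port constants from the data as the pipeline does
segment_fleet <- function(fleet, gap_bridge_max_min = 240) {
  rec <- preprocess_vms(fleet$records, fleet$ports, fleet$areas,
                        observer = fleet$observer)
  rules <- port_rules(fleet$ports, gap_bridge_max_min = gap_bridge_max_min)
  rec <- assign_port_status(rec, rules)
  ts <- segment_trips(rec, rules)
  ts <- prune_short_trips(ts)
  hubs <- fleet$ports$port_id[!is.na(fleet$ports$start_nmi)]
  konst <- do.call(rbind, lapply(hubs, function(p)
    suppressWarnings(estimate_inport_constants(ts, p))))
  trip_metrics(ts, constants = konst)
}

segmented_clean <- function() {
  if (is.null(.fleets$clean_ts)) .fleets$clean_ts <- segment_fleet(clean_fleet())
  .fleets$clean_ts
}

segmented_mix <- function() {
  if (is.null(.fleets$mix_ts)) .fleets$mix_ts <- segment_fleet(small_fleet())
  .fleets$mix_ts
}

# acceptance-scale fleets (>= 500 trips); built on first use
big_mix_fleet <- function() {
  if (is.null(.fleets$big)) {
    .fleets$big <- simulate_fleet(n_vessels = 70, trips_per_vessel = 8,
                                  seed = 42)
    .fleets$big_ts <- segment_fleet(.fleets$big)
  }
  list(fleet = .fleets$big, ts = .fleets$big_ts)
}

big_clean_fleet <- function() {
  if (is.null(.fleets$bigclean)) {
    .fleets$bigclean <- simulate_fleet(
      n_vessels = 64, trips_per_vessel = 8,
      sampling = sampling_model(jitter_fraction_35_60 = 0,
                                long_gap_fraction = 0),
      seed = 24)
    .fleets$bigclean_ts <- segment_fleet(.fleets$bigclean)
  }
  list(fleet = .fleets$bigclean, ts = .fleets$bigclean_ts)
}
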