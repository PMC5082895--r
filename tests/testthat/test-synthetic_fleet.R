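# Registry with two ports placed exactly 120 nmi apart for arithmetic checks.
two_port_registry <- function() {
  a <- c(-166, 54)
  b <- gc_destination(a[1], a[2], 90, 120)
  build_port_registry(data.frame(
    port_id = c("pa", "pb"), lat = c(a[2], b[1, "lat"]),
    lon = c(a[1], b[1, "lon"]), radius_nmi = c(3, 3), region = "BS"))
}

test_that("a straight 12-h transit covers speed x time", {
  ports <- two_port_registry()
  set.seed(1)
  st <- simulate_trip("V1", list(behavior = "transit", start_port = "pa",
                                 end_port = "pb", duration_min = 720), ports)
  # 120 nmi in 12 h -> 10 kn straight line; 1-min polyline length matches
  expect_equal(st$truth$true_distance_nmi, 120, tolerance = 0.01)
  expect_equal(as.numeric(difftime(st$truth$true_end, st$truth$true_start,
                                   units = "mins")), 720)
  # starts and ends at the dock coordinates
  n <- nrow(st$track)
  expect_equal(c(st$track$lon[1], st$track$lat[1]), c(-166, 54))
  expect_equal(st$track$lon[n], ports$lon[2], tolerance = 1e-9)
})

test_that("an unreachable transit errors", {
  ports <- two_port_registry()
  expect_error(simulate_trip("V1", list(behavior = "transit",
                                        start_port = "pa", end_port = "pb",
                                        duration_min = 300), ports),
               "unreachable")
})

test_that("fishing trips contain slow sinuous legs and respect duration", {
  ports <- build_port_registry("bering_toy")
  set.seed(2)
  st <- simulate_trip("V1", list(behavior = "afa_fishing",
                                 start_port = "dutch_harbor",
                                 end_port = "dutch_harbor",
                                 duration_min = 2880, ground_bearing = 0),
                      ports)
  expect_true(any(st$track$state == "fishing"))
  # per-minute speeds during fishing lie in the 0-5 kn band
  fidx <- which(st$track$state == "fishing")
  fidx <- fidx[fidx > 1]
  v <- gc_dist_nmi(st$track$lon[fidx - 1], st$track$lat[fidx - 1],
                   st$track$lon[fidx], st$track$lat[fidx]) * 60
  expect_true(all(v <= 5 + 1e-6))
  expect_equal(nrow(st$track), 2881)
})

test_that("the same seed reproduces the same track", {
  ports <- build_port_registry("bering_toy")
  plan <- list(behavior = "afa_fishing", start_port = "akutan",
               end_port = "akutan", duration_min = 1500)
  set.seed(33); a <- simulate_trip("V1", plan, ports)
  set.seed(33); b <- simulate_trip("V1", plan, ports)
  expect_identical(a, b)
})

test_that("sampled records are points of the generating track", {
  fleet <- clean_fleet()
  tr <- fleet$truth[1, ]
  r <- fleet$records[fleet$records$vessel_id == tr$vessel_id &
                       fleet$records$timestamp >= tr$true_start &
                       fleet$records$timestamp <= tr$true_end, ]
  expect_gt(nrow(r), 10)
  # sampled polyline can only be shorter than the true path
  expect_lte(oracle_path_nmi(r), tr$true_distance_nmi + 1e-6)
})

test_that("sampling without noise gives exactly nominal intervals", {
  ports <- build_port_registry("bering_toy")
  set.seed(3)
  st <- simulate_trip("V1", list(behavior = "transit", start_port = "dutch_harbor",
                                 end_port = "akutan", duration_min = 180), ports)
  rec <- sample_vms(st$track, sampling_model(jitter_fraction_35_60 = 0,
                                             long_gap_fraction = 0))
  expect_equal(unique(diff(as.numeric(rec$timestamp)) / 60), 30)
})

test_that("degenerate all-gap sampling produces only the fixed gap", {
  ports <- build_port_registry("bering_toy")
  set.seed(4)
  st <- simulate_trip("V1", list(behavior = "afa_fishing",
                                 start_port = "dutch_harbor",
                                 end_port = "dutch_harbor",
                                 duration_min = 2000), ports)
  m <- sampling_model(jitter_fraction_35_60 = 0, long_gap_fraction = 1,
                      gap_lengths_min = 240, gap_weights = 1)
  rec <- sample_vms(st$track, m)
  expect_equal(unique(diff(as.numeric(rec$timestamp)) / 60), 240)
})

test_that("empirical interval fractions fall within binomial error", {
  # stationary 1-min track long enough for ~10,000 sampled intervals
  n_min <- 10000 * 30
  track <- data.frame(vessel_id = "V1",
                      timestamp = utc("2013-01-01 00:00:00") + 60 * (0:n_min),
                      lon = -166, lat = 55, state = "dock")
  set.seed(5)
  rec <- sample_vms(track, sampling_model())
  iv <- diff(as.numeric(rec$timestamp)) / 60
  n <- length(iv)
  for (case in list(c(0.089, 35, 60), c(0.021, 61, Inf))) {
    p <- case[1]
    obs <- mean(iv >= case[2] & iv <= case[3])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se)
  }
})

test_that("invalid sampling fractions are rejected", {
  expect_error(sampling_model(jitter_fraction_35_60 = 0.7,
                              long_gap_fraction = 0.4), "fractions")
  expect_error(sampling_model(jitter_fraction_35_60 = -0.1), "fractions")
})

test_that("observer emission honors coverage and error modes", {
  fleet <- clean_fleet()
  truth <- fleet$truth
  set.seed(6)
  ob <- emit_observer_records(truth, coverage = 1, clock_sd_min = 0)
  expect_equal(nrow(ob), nrow(truth))
  expect_equal(ob$obs_start, truth$true_start)
  expect_equal(ob$obs_end, truth$true_end)
  expect_equal(nrow(emit_observer_records(truth, coverage = 0)), 0)
  expect_error(emit_observer_records(truth, coverage = 1.2), "coverage")
  # late start shortens the observed duration by exactly that many minutes
  late <- emit_observer_records(truth, coverage = 1, late_start_min = 120)
  expect_equal(as.numeric(difftime(late$obs_end, late$obs_start, units = "mins")),
               as.numeric(difftime(truth$true_end, truth$true_start,
                                   units = "mins")) - 120)
  # dock extension lengthens it
  dock <- emit_observer_records(truth, coverage = 1, dock_extension_min = 60)
  expect_equal(as.numeric(difftime(dock$obs_end, dock$obs_start, units = "mins")),
               as.numeric(difftime(truth$true_end, truth$true_start,
                                   units = "mins")) + 60)
})

test_that("fish tickets cover fishing trips only, with usable fields", {
  fleet <- clean_fleet()
  fish <- fleet$truth[fleet$truth$behavior %in% c("afa_fishing", "other_fishing"), ]
  expect_equal(nrow(fleet$tickets), nrow(fish))
  expect_equal(fleet$tickets$port, fish$end_port)
  expect_equal(fleet$tickets$landing_date, as.Date(fish$true_end))
  expect_true(all(fleet$tickets$program[fish$behavior == "afa_fishing"] == "AFA"))
  expect_true(all(nchar(fleet$tickets$stat_areas[fleet$tickets$program == "AFA"]) > 0))
  # date-swap corruption makes the window clearly incorrect
  set.seed(7)
  bad <- emit_fish_tickets(fish, records = NULL, areas = NULL,
                           date_swap_prob = 1)
  expect_true(all(bad$landing_date < bad$fishing_start_date))
})
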