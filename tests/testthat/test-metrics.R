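test_that("dock extrapolation follows distance / speed with a floor", {
  # boundary already at the dock: nothing to add
  expect_equal(extrapolate_to_port(0, 4), list(add_nmi = 0, add_min = 0))
  # 2 nmi at 4 kn: +2 nmi, +30 min
  ex <- extrapolate_to_port(2, 4)
  expect_equal(ex$add_nmi, 2)
  expect_equal(ex$add_min, 30)
  # near-stationary adjacent segment: the 0.5-kn floor bounds added time
  ex <- extrapolate_to_port(1, 0.1)
  expect_equal(ex$add_min, 120)
})

test_that("the measurement-error bound is twice the interval minus two", {
  expect_equal(measurement_error_bound(30), 58)
  expect_equal(measurement_error_bound(1), 0)
  expect_equal(measurement_error_bound(60), 118)
  expect_error(measurement_error_bound(0), "at least 1")
  # exact identity over a sweep
  x <- 1:200
  expect_true(all(measurement_error_bound(x) - 2 * x + 2 == 0))
})

test_that("hub-to-hub metrics add constants in place of the buffer span", {
  # constructed trip: all records outside the 10-nmi buffer of a synthetic
  # hub pair, so constants are added to the raw span untrimmed
  ports <- build_port_registry(data.frame(
    port_id = c("h1", "h2"), lat = c(54, 54), lon = c(-166, -164),
    radius_nmi = 10, region = "BS",
    start_nmi = 10, start_min = 80, end_nmi = 10, end_min = 80))
  a <- gc_destination(-166, 54, 90, 10.5)   # just beyond h1's buffer
  pts <- gc_destination(a[1], a[2], 90, 10 * (0:10))
  r <- records_from_coords(pts[, "lon"], pts[, "lat"], interval_min = 100)
  r <- derive_fields(r, ports)
  r$in_port <- FALSE
  ts <- structure(list(
    trips = data.frame(trip_id = "T1", vessel_id = "V1", start_row = 1L,
                       end_row = nrow(r), start_time = r$timestamp[1],
                       end_time = r$timestamp[nrow(r)],
                       start_port = "h1", end_port = "h2",
                       start_boundary = "inferred", end_boundary = "inferred",
                       n_records = nrow(r),
                       max_gap_min = 100, stringsAsFactors = FALSE),
    records = r), class = "trip_set", ports = ports)
  ts <- trip_metrics(ts)
  # records span 1,000 min and 100 nmi; plus 80 + 80 min and 10 + 10 nmi
  expect_equal(ts$trips$duration_min, 1000 + 160)
  expect_equal(ts$trips$distance_nmi, 100 + 20, tolerance = 1e-6)
})

test_that("estimated in-port constants recover known approach geometry", {
  # synthetic hub approach: 8 kn straight from the dock, records every 30
  # min -> expect ~(10 nmi, 75 min) for the 10-nmi buffer
  ports <- build_port_registry(data.frame(
    port_id = c("h1", "h2"), lat = c(54, 54), lon = c(-166, -160),
    radius_nmi = 10, region = "BS",
    start_nmi = 13, start_min = 101, end_nmi = 12, end_min = 92))
  pts <- gc_destination(-166, 54, 90, 4 * (0:10))     # 8 kn outbound
  r <- records_from_coords(pts[, "lon"], pts[, "lat"])
  r <- derive_fields(r, ports)
  ts <- structure(list(
    trips = data.frame(trip_id = "T1", vessel_id = "V1", start_row = 1L,
                       end_row = nrow(r), start_time = r$timestamp[1],
                       end_time = r$timestamp[nrow(r)],
                       start_port = "h1", end_port = NA_character_,
                       start_boundary = "in_port", end_boundary = "open",
                       n_records = nrow(r), max_gap_min = 30,
                       stringsAsFactors = FALSE),
    records = r), class = "trip_set", ports = ports)
  k <- estimate_inport_constants(ts, "h1")
  expect_equal(k$n_out, 1)
  expect_equal(k$start_nmi, 10, tolerance = 0.01)
  expect_equal(k$start_min, 75, tolerance = 0.5)
  # a traversal with a 45-min interval does not qualify: defaults retained
  r2 <- r
  r2$timestamp[3] <- r2$timestamp[3] + 15 * 60
  ts$records <- derive_fields(r2, ports)
  expect_warning(k2 <- estimate_inport_constants(ts, "h1"), "defaults")
  expect_equal(k2$start_nmi, 13)
  expect_equal(k2$start_min, 101)
})

test_that("gap-free synthetic distances track the true path length", {
  ts <- segmented_clean()
  fleet <- clean_fleet()
  rec <- truth_recovery(ts, fleet$truth)
  acc <- rec$accounting
  i <- match(acc$trip_id, ts$trips$trip_id)
  # sampled-polyline distance is below truth (straightening) but within a
  # few percent at 30-min sampling of mostly transit/fishing behavior
  ratio <- ts$trips$distance_nmi[i] / fleet$truth$true_distance_nmi
  expect_true(all(ratio < 1.05))
  expect_true(mean(ratio) > 0.8)
})

test_that("observer comparison reproduces the worked timing example", {
  # observed trip starts 12:01; records at 12:00 (dock) and 12:30 (at sea):
  # the trip clock starts at 12:30, a 29-min start discrepancy
  ports <- build_port_registry("bering_toy")
  dh <- ports[ports$port_id == "king_cove", ]   # small port: no constants
  off <- gc_destination(dh$lon, dh$lat, 0, c(4, 8, 12, 16, 20, 24, 28))
  lon <- c(dh$lon, off[, "lon"]); lat <- c(dh$lat, off[, "lat"])
  r <- records_from_coords(lon, lat, start = utc("2013-03-01 12:00:00"))
  rules <- port_rules(ports)
  r <- assign_port_status(derive_fields(r, ports), rules)
  expect_true(r$in_port[1])
  ts <- segment_trips(r, rules)
  ts <- trip_metrics(ts)
  ob <- data.frame(obs_trip_id = "o1", vessel_id = "V1",
                   obs_start = utc("2013-03-01 12:01:00"),
                   obs_end = utc("2013-03-01 15:30:00"))
  ts$records <- match_observer(ts$records, ob)
  cmp <- compare_with_observer(ts, ob)
  expect_equal(cmp$summary$n, 1)
  # start discrepancy 29 min (end coincides with the last record)
  expect_equal(cmp$comparisons$diff_min, -29)
  expect_true(cmp$comparisons$within_bound)
})

test_that("clean fleets sit inside the error bound with rank correlation 1", {
  ts <- segmented_clean()
  fleet <- clean_fleet()
  cmp <- compare_with_observer(ts, fleet$observer)
  expect_gt(cmp$summary$n, 10)
  expect_equal(cmp$summary$share_within_bound, 1)
  expect_gt(cmp$summary$spearman_rho, 0.99)
  expect_lt(abs(cmp$summary$aggregate_pct_error), 1.5)
})

test_that("identical estimated and observed durations give zero error", {
  ts <- segmented_clean()
  fleet <- clean_fleet()
  cmp <- compare_with_observer(ts, fleet$observer)
  fake <- cmp$comparisons
  fake$est_duration_min <- fake$obs_duration_min
  fake$diff_min <- 0; fake$pct_error <- 0
  expect_true(all(abs(fake$diff_min) <= fake$error_bound_min))
})

test_that("bias regression recovers an injected piecewise bias", {
  set.seed(31)
  obs <- c(runif(120, 250, 650), runif(120, 800, 6000))
  est <- obs
  est[obs < 700] <- est[obs < 700] * 1.10          # +10% below the break
  est <- est * exp(rnorm(length(est), 0, 0.01))
  cmp <- data.frame(est_duration_min = est, obs_duration_min = obs)
  fit <- bias_correction_regression(cmp)
  # slope ~1, intercept ~ -log(1.1) below the breakpoint
  expect_equal(unname(coef(fit$models$below)["x"]), 1, tolerance = 0.05)
  expect_equal(unname(coef(fit$models$below)[1]), -log(1.1), tolerance = 0.15)
  # correction reduces the aggregate and trip-level error
  expect_lt(abs(fit$summary$aggregate_pct_error_post),
            abs(fit$summary$aggregate_pct_error_pre))
  expect_lt(fit$summary$mean_abs_pct_error_post,
            fit$summary$mean_abs_pct_error_pre)
})

test_that("unbiased pairs give identity-like fits; degenerate input warns", {
  set.seed(32)
  obs <- c(runif(100, 250, 650), runif(100, 800, 6000))
  est <- obs * exp(rnorm(200, 0, 0.005))
  fit <- bias_correction_regression(
    data.frame(est_duration_min = est, obs_duration_min = obs))
  expect_equal(unname(coef(fit$models$below)["x"]), 1, tolerance = 0.05)
  expect_equal(unname(coef(fit$models$above)["x"]), 1, tolerance = 0.05)
  # constant estimates: identity correction with a warning
  cmp <- data.frame(est_duration_min = rep(500, 60),
                    obs_duration_min = runif(60, 400, 600))
  expect_warning(fit2 <- bias_correction_regression(cmp), "degenerate")
  expect_equal(fit2$corrected$corrected_duration_min, cmp$est_duration_min)
  expect_error(bias_correction_regression(cmp[1:10, ]), "50")
})
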