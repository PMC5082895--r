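hub_ports <- function() build_port_registry("bering_toy")

# build a derived+status record stream from raw coords around Dutch Harbor
status_records <- function(lon, lat, interval_min = 30, rules = NULL,
                           ports = hub_ports()) {
  if (is.null(rules)) rules <- port_rules(ports)
  r <- derive_fields(records_from_coords(lon, lat, interval_min = interval_min),
                     ports)
  assign_port_status(r, rules)
}

test_that("in-port assignment follows radius, speed and dwell rules", {
  ports <- hub_ports()
  dh <- ports[ports$port_id == "dutch_harbor", ]
  # slow record 5 nmi from a 10-nmi hub: in port
  p5 <- gc_destination(dh$lon, dh$lat, 0, 5)
  p5b <- gc_destination(p5[1], p5[2], 90, 0.1)       # 0.2 kn over 30 min
  r <- status_records(c(p5[1], p5b[1]), c(p5[2], p5b[2]))
  expect_true(r$in_port[2])
  # fast record crossing the same radius: not in port
  q1 <- gc_destination(dh$lon, dh$lat, 0, 5)
  q0 <- gc_destination(q1[1], q1[2], 270, 5)         # 10 kn approach
  r <- status_records(c(q0[1], q1[1]), c(q0[2], q1[2]))
  expect_false(r$in_port[2])
  # 5 nmi from a small port with radius 3: outside, regardless of speed
  kc <- ports[ports$port_id == "king_cove", ]
  s5 <- gc_destination(kc$lon, kc$lat, 180, 5)
  s5b <- gc_destination(s5[1], s5[2], 90, 0.1)
  r <- status_records(c(s5[1], s5b[1]), c(s5[2], s5b[2]))
  expect_false(any(r$in_port))
})

test_that("corridor records at speed are never in-port", {
  ports <- hub_ports()
  dh <- ports[ports$port_id == "dutch_harbor", ]
  # corridor polygon covering a box north-east of Dutch Harbor
  cor <- data.frame(area_id = "corr",
                    lon = dh$lon + c(-0.1, 0.6, 0.6, -0.1),
                    lat = dh$lat + c(0.01, 0.01, 0.3, 0.3))
  rules <- port_rules(ports, corridors = cor)
  # 10-kn transit through the corridor inside the hub radius
  a <- gc_destination(dh$lon, dh$lat, 40, 4)
  b <- gc_destination(a[1], a[2], 60, 5)
  r <- status_records(c(a[1], b[1]), c(a[2], b[2]), rules = rules)
  expect_false(any(r$in_port))
})

test_that("a clean dock-to-dock stream yields one trip with correct ports", {
  ts <- segmented_clean()
  fleet <- clean_fleet()
  rec <- truth_recovery(ts, fleet$truth)
  expect_equal(unname(rec$counts[["recovered"]]), nrow(fleet$truth))
  expect_equal(rec$one_to_one, 1)
  # recovered boundaries within one nominal interval of truth
  acc <- rec$accounting
  i <- match(acc$trip_id, ts$trips$trip_id)
  expect_true(all(abs(as.numeric(difftime(ts$trips$start_time[i],
                                          acc$true_start, units = "mins"))) <= 31))
  expect_true(all(abs(as.numeric(difftime(ts$trips$end_time[i],
                                          acc$true_end, units = "mins"))) <= 31))
  # ports recovered exactly (accounting rows follow truth order)
  expect_equal(ts$trips$start_port[i], fleet$truth$start_port)
  expect_equal(ts$trips$end_port[i], fleet$truth$end_port)
})

test_that("a gap spanning the whole port visit splits into two trips", {
  ports <- hub_ports()
  dh <- ports[ports$port_id == "dutch_harbor", ]
  # inbound 20 nmi east of port, 6-h silence over the visit, outbound
  # 20 nmi west: flanks ~40 nmi apart on opposite sides
  inb <- gc_destination(dh$lon, dh$lat, 90, c(30, 25, 20))
  outb <- gc_destination(dh$lon, dh$lat, 270, c(20, 25, 30))
  lon <- c(inb[, "lon"], outb[, "lon"]); lat <- c(inb[, "lat"], outb[, "lat"])
  r <- records_from_coords(lon, lat)
  r$timestamp[4:6] <- r$timestamp[4:6] + 6 * 3600    # the 6-h gap
  rules <- port_rules(ports)
  r <- assign_port_status(derive_fields(r, ports), rules)
  ts <- segment_trips(r, rules)
  expect_equal(nrow(ts$trips), 2)
  expect_equal(ts$trips$end_port[1], "dutch_harbor")
  expect_equal(ts$trips$start_port[2], "dutch_harbor")
  expect_equal(ts$trips$end_boundary[1], "inferred")
})

test_that("passing a small port without slowing does not split a trip", {
  ports <- hub_ports()
  kc <- ports[ports$port_id == "king_cove", ]
  # steady 10-kn track passing 8 nmi south of a 3-nmi-radius port
  start <- gc_destination(kc$lon, kc$lat, 180, 8)
  brg <- 90
  pts <- gc_destination(start[1], start[2], brg, 5 * (-6:6))
  r <- status_records(pts[, "lon"], pts[, "lat"])
  rules <- port_rules(ports)
  ts <- segment_trips(r, rules)
  expect_equal(nrow(ts$trips), 1)
})

test_that("a vessel with no in-port records yields one open trip", {
  pts <- gc_destination(-168, 56.5, 90, 5 * (0:9))
  r <- status_records(pts[, "lon"], pts[, "lat"])
  expect_false(any(r$in_port))
  ts <- segment_trips(r, port_rules(hub_ports()))
  expect_equal(nrow(ts$trips), 1)
  expect_equal(ts$trips$start_boundary, "open")
  expect_true(is.na(ts$trips$start_port))
})

test_that("every at-sea record belongs to exactly one trip", {
  ts <- segmented_mix()
  at_sea <- !ts$records$in_port
  # before pruning, every at-sea record is assigned (pruning may null a few)
  fleet <- small_fleet()
  rules <- port_rules(fleet$ports)
  rec <- preprocess_vms(fleet$records, fleet$ports, fleet$areas)
  rec <- assign_port_status(rec, rules)
  raw <- segment_trips(rec, rules)
  expect_true(all(!is.na(raw$records$trip_id[!raw$records$in_port])))
  # no trip spans two vessels
  for (i in seq_len(nrow(raw$trips))) {
    v <- raw$records$vessel_id[raw$trips$start_row[i]:raw$trips$end_row[i]]
    expect_equal(length(unique(v)), 1)
  }
})

test_that("trips of four or fewer records are pruned at the boundary", {
  ts <- segmented_clean()
  t4 <- ts$trips[1, ]; t4$n_records <- 4
  t5 <- ts$trips[2, ]; t5$n_records <- 5
  fake <- ts; fake$trips <- rbind(t4, t5)
  out <- prune_short_trips(fake)
  expect_equal(nrow(out$trips), 1)
  expect_equal(out$trips$n_records, 5)
  expect_equal(attr(out$trips, "pruned"), 1)
  # empty list stays empty
  fake$trips <- fake$trips[0, ]
  expect_equal(nrow(prune_short_trips(fake)$trips), 0)
})
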