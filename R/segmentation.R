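#' Port detection rules
#'
#' Per-port rules controlling in-port assignment and gap handling. Hub
#' ports with in-port travel constants (large protected bays) are in-port
#' by distance alone; smaller exposed ports sit near fishing grounds and
#' transit routes, so distance must be confirmed by slow speed or a dwell.
#' Declared transit-corridor polygons (e.g. the run between two hub ports)
#' suppress in-port status for vessels moving through at speed.
#'
#' @param ports A port registry (radii are taken from it).
#' @param speed_ceiling_kn Speed at or below which a record inside a port
#'   radius is confirmed in-port.
#' @param min_dwell_min Minimum time a vessel must linger inside a radius
#'   for a dwell to confirm in-port status.
#' @param gap_bridge_max_min Transmission gaps at most this long are kept
#'   interior to a trip; longer gaps trigger port-visit inference.
#' @param corridors Optional corridor polygons in [make_area_grid()] long
#'   format.
#' @return A `port_rules` list.
#' @export
port_rules <- function(ports, speed_ceiling_kn = 2, min_dwell_min = 60,
                       gap_bridge_max_min = 240, corridors = NULL) {
  stopifnot(inherits(ports, "port_registry"))
  if (gap_bridge_max_min < 1) stop("gap_bridge_max_min must be positive")
  structure(list(ports = ports,
                 speed_ceiling_kn = speed_ceiling_kn,
                 min_dwell_min = min_dwell_min,
                 gap_bridge_max_min = gap_bridge_max_min,
                 corridors = corridors),
            class = "port_rules")
}

#' Assign in-port status to records
#'
#' A record is in-port when its distance to the nearest port is within that
#' port's radius and the stop is confirmed by slow speed (at or below the
#' ceiling) or by a dwell of at least `min_dwell_min` inside the radius —
#' distance alone cannot distinguish entering port from passing it.
#' Records inside a declared transit corridor are in-port only when both
#' slow and dwelling.
#'
#' @param records Records with derived fields.
#' @param rules A [port_rules()] object.
#' @return Records with a logical `in_port` column.
#' @export
assign_port_status <- function(records, rules) {
  stopifnot(inherits(rules, "port_rules"))
  ports <- rules$ports
  if (!nrow(records)) { records$in_port <- logical(0); return(records) }
  if (any(is.na(match(records$nearest_port, ports$port_id))))
    stop("records reference ports missing from the rule set")
  radius <- ports$radius_nmi[match(records$nearest_port, ports$port_id)]
  in_radius <- records$dist_port_nmi <= radius
  slow <- is.na(records$speed_kn) | records$speed_kn <= rules$speed_ceiling_kn
  # dwell: per vessel, maximal runs of consecutive records inside the same
  # port radius whose time span reaches min_dwell_min
  dwell <- rep(FALSE, nrow(records))
  run_id <- cumsum(c(TRUE, records$vessel_id[-1] != records$vessel_id[-nrow(records)] |
                       records$nearest_port[-1] != records$nearest_port[-nrow(records)] |
                       !in_radius[-1] | !in_radius[-nrow(records)]))
  for (ix in split(seq_len(nrow(records)), run_id)) {
    if (!in_radius[ix[1]]) next
    # records still in motion at the run edges are arrival/departure
    # transit, not dwell: the head is judged by where the vessel goes next
    # (forward speed), the tail by where it came from (backward speed)
    flag <- rep(TRUE, length(ix))
    bwd <- records$speed_kn[ix]
    fwd <- c(bwd[-1], NA)
    i <- 1
    while (i <= length(ix) && !is.na(fwd[i]) && fwd[i] > rules$speed_ceiling_kn) {
      flag[i] <- FALSE; i <- i + 1
    }
    j <- length(ix)
    while (j >= i && !is.na(bwd[j]) && bwd[j] > rules$speed_ceiling_kn) {
      flag[j] <- FALSE; j <- j - 1
    }
    core <- ix[flag]
    if (!length(core)) next
    span <- as.numeric(difftime(records$timestamp[core[length(core)]],
                                records$timestamp[core[1]], units = "mins"))
    if (span < rules$min_dwell_min) next
    # lingering, not steadily crossing the buffer: the core's average
    # speed over its own path must also sit at or below the ceiling
    path <- sum(records$dist_prev_nmi[core[-1]], na.rm = TRUE)
    if (path / (span / 60) <= rules$speed_ceiling_kn) dwell[core] <- TRUE
  }
  in_corridor <- if (is.null(rules$corridors)) rep(FALSE, nrow(records)) else
    !is.na(assign_stat_area(rules$corridors, records$lon, records$lat))
  in_port <- in_radius & (slow | dwell)
  in_port[in_corridor] <- in_radius[in_corridor] &
    (slow[in_corridor] & dwell[in_corridor])
  records$in_port <- in_port
  records
}

# can a hidden port visit explain a long gap between records i and j?
# returns the inferred port id or NA
infer_gap_port <- function(records, i, j, rules) {
  ports <- rules$ports
  gap_hr <- as.numeric(difftime(records$timestamp[j], records$timestamp[i],
                                units = "hours"))
  if (gap_hr <= 0) return(NA_character_)
  d12 <- gc_dist_nmi(records$lon[i], records$lat[i], records$lon[j], records$lat[j])
  best <- NA_character_; best_detour <- Inf
  for (k in seq_len(nrow(ports))) {
    d1 <- gc_dist_nmi(records$lon[i], records$lat[i], ports$lon[k], ports$lat[k])
    d2 <- gc_dist_nmi(records$lon[j], records$lat[j], ports$lon[k], ports$lat[k])
    detour <- d1 + d2
    if (detour / gap_hr > 14) next          # infeasible at the speed cap
    near_both <- d1 <= 1.5 * ports$radius_nmi[k] & d2 <= 1.5 * ports$radius_nmi[k]
    between <- FALSE
    if (!near_both && d12 > 0.1) {
      xt <- gc_cross_track_nmi(ports$lon[k], ports$lat[k],
                               records$lon[i], records$lat[i],
                               records$lon[j], records$lat[j])
      at <- geosphere::alongTrackDistance(
        cbind(records$lon[i], records$lat[i]),
        cbind(records$lon[j], records$lat[j]),
        cbind(ports$lon[k], ports$lat[k]), r = EARTH_RADIUS_M) / NMI_M
      between <- xt <= ports$radius_nmi[k] + 2 && at >= 0 && at <= d12
    }
    if ((near_both || between) && detour < best_detour) {
      best <- ports$port_id[k]; best_detour <- detour
    }
  }
  best
}

#' Segment a record stream into trips
#'
#' A trip is a maximal run of at-sea records, bracketed (where available)
#' by the adjacent in-port records, which supply the start and end ports.
#' Consecutive in-port records collapse into a single port visit.
#' Transmission gaps longer than `gap_bridge_max_min` inside an at-sea run
#' are tested for a hidden port visit: when a port lies between (or close
#' to both of) the flanking records and reaching it implies at most 14 kn,
#' the run is split into two trips sharing that inferred port; otherwise
#' the gap stays interior to one trip. Vessels with no in-port records
#' yield a single open trip with unknown ports.
#'
#' @param records Records with `in_port` assigned ([assign_port_status()]).
#' @param rules A [port_rules()] object.
#' @return A `trip_set`: list with `trips` (one row per trip: ids, times,
#'   ports, boundary metadata, `n_records`, `max_gap_min`) and `records`
#'   (the input, time-sorted, with a `trip_id` column).
#' @export
segment_trips <- function(records, rules) {
  stopifnot(inherits(rules, "port_rules"))
  ord <- order(records$vessel_id, records$timestamp)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  trips <- list()
  for (v in unique(records$vessel_id)) {
    vi <- which(records$vessel_id == v)
    ip <- records$in_port[vi]
    if (!any(!ip)) next                       # vessel never left port
    # at-sea runs over vessel-local indices
    r <- rle(ip)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (s in seq_along(r$values)) {
      if (r$values[s]) next                   # an in-port run, not a trip
      a <- starts[s]; b <- ends[s]
      i0 <- if (a > 1) vi[a - 1] else NA      # boundary in-port records
      i1 <- if (b < length(vi)) vi[b + 1] else NA
      seg_start <- if (is.na(i0)) vi[a] else i0
      seg_end <- if (is.na(i1)) vi[b] else i1
      # long gaps inside this run: try port inference, splitting the run
      run <- seg_start:seg_end
      iv <- as.numeric(difftime(records$timestamp[run[-1]],
                                records$timestamp[run[-length(run)]],
                                units = "mins"))
      cut_after <- integer(0); cut_port <- character(0)
      big <- which(iv > rules$gap_bridge_max_min)
      for (g in big) {
        i <- run[g]; j <- run[g + 1]
        if (records$in_port[i] || records$in_port[j]) next
        p <- infer_gap_port(records, i, j, rules)
        if (!is.na(p)) { cut_after <- c(cut_after, i); cut_port <- c(cut_port, p) }
      }
      seg_starts <- c(seg_start, cut_after + 1L)
      seg_ends <- c(cut_after, seg_end)
      for (q in seq_along(seg_starts)) {
        s0 <- seg_starts[q]; s1 <- seg_ends[q]
        sb <- if (q > 1) "inferred" else if (!is.na(i0)) "in_port" else "open"
        eb <- if (q < length(seg_starts)) "inferred" else
          if (!is.na(i1)) "in_port" else "open"
        sp <- switch(sb, in_port = records$nearest_port[s0],
                     inferred = cut_port[q - 1], NA_character_)
        ep <- switch(eb, in_port = records$nearest_port[s1],
                     inferred = cut_port[q], NA_character_)
        trips[[length(trips) + 1]] <- make_trip(records, s0, s1, sb, eb, sp, ep)
      }
    }
  }
  trips <- if (length(trips)) do.call(rbind, trips) else empty_trips()
  if (nrow(trips)) {
    trips$trip_id <- sprintf("T%05d", seq_len(nrow(trips)))
    records$trip_id <- NA_character_
    for (i in seq_len(nrow(trips)))
      records$trip_id[trips$start_row[i]:trips$end_row[i]] <-
        trips$trip_id[i]
  } else records$trip_id <- NA_character_
  structure(list(trips = trips, records = records), class = "trip_set",
            ports = rules$ports)
}

make_trip <- function(records, s0, s1, sb, eb, sp, ep) {
  run <- s0:s1
  iv <- if (length(run) > 1)
    as.numeric(difftime(records$timestamp[run[-1]],
                        records$timestamp[run[-length(run)]], units = "mins"))
  else numeric(0)
  data.frame(
    trip_id = NA_character_, vessel_id = records$vessel_id[s0],
    start_row = s0, end_row = s1,
    start_time = records$timestamp[s0], end_time = records$timestamp[s1],
    start_port = sp, end_port = ep,
    start_boundary = sb, end_boundary = eb,
    n_records = length(run),
    max_gap_min = if (length(iv)) max(iv) else NA_real_,
    stringsAsFactors = FALSE)
}

empty_trips <- function() {
  data.frame(trip_id = character(0), vessel_id = character(0),
             start_row = integer(0), end_row = integer(0),
             start_time = as.POSIXct(character(0), tz = "UTC"),
             end_time = as.POSIXct(character(0), tz = "UTC"),
             start_port = character(0), end_port = character(0),
             start_boundary = character(0), end_boundary = character(0),
             n_records = integer(0), max_gap_min = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.trip_set <- function(x, ...) {
  cat("<trip_set> ", nrow(x$trips), " trips over ",
      length(unique(x$trips$vessel_id)), " vessels; ",
      nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Records belonging to one trip
#' @param ts A `trip_set`.
#' @param trip_id A trip id present in `ts$trips`.
#' @return The trip's records, time-ordered (boundary in-port records
#'   included).
#' @export
trip_records <- function(ts, trip_id) {
  i <- match(trip_id, ts$trips$trip_id)
  if (is.na(i)) stop("unknown trip id: ", trip_id)
  ts$records[ts$trips$start_row[i]:ts$trips$end_row[i], , drop = FALSE]
}

#' Drop trips with too few records
#'
#' Short spurious trips (typically repeated crossings of a hub threshold)
#' of four or fewer records are removed.
#'
#' @param ts A `trip_set`.
#' @param min_records Minimum records for a trip to be kept.
#' @return The `trip_set` with short trips dropped; the count removed is in
#'   attribute `"pruned"` of the `trips` element.
#' @export
prune_short_trips <- function(ts, min_records = 5) {
  keep <- ts$trips$n_records >= min_records
  pruned <- sum(!keep)
  ts$trips <- ts$trips[keep, , drop = FALSE]
  rownames(ts$trips) <- NULL
  ts$records$trip_id[!ts$records$trip_id %in% ts$trips$trip_id] <- NA_character_
  attr(ts$trips, "pruned") <- pruned
  ts
}
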