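#' VMS sampling model
#'
#' Describes how a transponder samples a continuous vessel track: a nominal
#' transmission interval plus two empirically motivated departures — a
#' fraction of intervals jittered to 35–60 min and a smaller fraction of
#' long gaps. Defaults mirror the interval mix observed in Bering Sea
#' pollock VMS streams (8.9% of records at 35–60 min, 2.1% longer).
#'
#' @param nominal_interval_min Nominal transmission interval, minutes.
#' @param jitter_fraction_35_60 Probability an interval is drawn uniformly
#'   from 35–60 min instead of the nominal interval.
#' @param long_gap_fraction Probability an interval is a long gap drawn from
#'   `gap_lengths_min` with weights `gap_weights`.
#' @param gap_lengths_min Candidate gap lengths, minutes.
#' @param gap_weights Sampling weights for `gap_lengths_min` (normalised).
#' @return A `sampling_model` list.
#' @export
sampling_model <- function(nominal_interval_min = 30,
                           jitter_fraction_35_60 = 0.089,
                           long_gap_fraction = 0.021,
                           gap_lengths_min = c(90, 120, 150, 240, 480),
                           gap_weights = c(16, 8, 4, 2, 1)) {
  if (nominal_interval_min <= 0) stop("nominal_interval_min must be positive")
  fr <- c(jitter_fraction_35_60, long_gap_fraction)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("interval fractions must lie in [0,1] and sum to at most 1")
  if (length(gap_lengths_min) != length(gap_weights))
    stop("gap_lengths_min and gap_weights lengths differ")
  structure(list(nominal_interval_min = nominal_interval_min,
                 jitter_fraction_35_60 = jitter_fraction_35_60,
                 long_gap_fraction = long_gap_fraction,
                 gap_lengths_min = gap_lengths_min,
                 gap_weights = gap_weights / sum(gap_weights)),
            class = "sampling_model")
}

# positions after 1..n_min minutes from (lon,lat) on a fixed bearing
leg_points <- function(lon, lat, bearing, speed_kn, n_min) {
  if (n_min <= 0) return(matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("lon", "lat"))))
  gc_destination(lon, lat, bearing, speed_kn / 60 * seq_len(n_min))
}

# chunked pursuit toward a target: re-aims every `chunk` minutes, and exactly
# hits the target on the final minute (closing speeds stay near `speed_kn`)
pursuit_points <- function(lon, lat, tlon, tlat, n_min, chunk = 15) {
  if (n_min <= 0) return(matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("lon", "lat"))))
  pts <- matrix(NA_real_, nrow = n_min, ncol = 2,
                dimnames = list(NULL, c("lon", "lat")))
  done <- 0
  clon <- lon; clat <- lat
  while (done < n_min) {
    left <- n_min - done
    d <- gc_dist_nmi(clon, clat, tlon, tlat)
    v <- d / (left / 60)                   # speed needed to arrive on time
    step <- min(chunk, left)
    b <- gc_bearing(clon, clat, tlon, tlat)
    p <- leg_points(clon, clat, b, v, step)
    pts[(done + 1):(done + step), ] <- p
    clon <- p[step, 1]; clat <- p[step, 2]
    done <- done + step
  }
  pts[n_min, ] <- c(tlon, tlat)            # land exactly at the dock
  pts
}

#' Simulate one ground-truthed vessel trip
#'
#' Generates a continuous dock-to-dock track at 1-min resolution using
#' great-circle dead reckoning, together with its truth record. Fishing
#' trips consist of transit legs (8–12 kn) out to a fishing ground and
#' sinuous slow legs (0.5–5 kn) on the ground; transits are straight
#' constant-speed runs between ports; tender trips transit with a long slow
#' loiter midway.
#'
#' @param vessel_id Vessel identifier.
#' @param plan List with `behavior` (`"afa_fishing"`, `"other_fishing"`,
#'   `"transit"`, `"tender"`), `start_port`, `end_port`, `duration_min`, and
#'   optionally `speed_kn` (transit) and `ground_bearing` (fishing).
#' @param ports A port registry.
#' @param t0 POSIXct (UTC) departure time.
#' @return List with `truth` (one-row data frame: vessel, behavior, true
#'   start/end, ports, `true_distance_nmi`) and `track` (1-min data frame:
#'   `timestamp`, `lon`, `lat`, `state`).
#' @export
simulate_trip <- function(vessel_id, plan, ports,
                          t0 = as.POSIXct("2013-01-15 06:00:00", tz = "UTC")) {
  behavior <- match.arg(plan$behavior,
                        c("afa_fishing", "other_fishing", "transit", "tender"))
  dur <- as.integer(round(plan$duration_min))
  if (is.null(dur) || dur <= 0) stop("plan duration must be positive")
  sp0 <- port_row(ports, plan$start_port)
  sp1 <- port_row(ports, plan$end_port)
  port_dist <- gc_dist_nmi(sp0$lon, sp0$lat, sp1$lon, sp1$lat)
  max_kn <- 12
  if (port_dist / (dur / 60) > max_kn)
    stop("end port unreachable at ", max_kn, " kn within plan duration")

  if (behavior == "transit") {
    # straight constant-speed run; speed set so arrival is exactly on time
    pts <- pursuit_points(sp0$lon, sp0$lat, sp1$lon, sp1$lat, dur)
    state <- rep("transit", dur)
  } else if (behavior == "tender") {
    # transit out to a loiter station, slow wander there, then run home,
    # breaking off the loiter early enough to make the dock in time
    v_t <- runif(1, 8, 12)
    # loiter station offshore, clear of every port's buffer
    stn <- NULL
    for (try in 1:50) {
      cand <- gc_destination(sp0$lon, sp0$lat, runif(1, 0, 360),
                             max(port_dist * 0.5, runif(1, 15, 30)))
      dmin <- min(gc_dist_nmi(cand[1], cand[2], ports$lon, ports$lat) -
                    ports$radius_nmi)
      if (dmin > 3) { stn <- cand; break }
    }
    if (is.null(stn)) stop("no loiter station clear of port buffers")
    n_out <- max(1L, ceiling(gc_dist_nmi(sp0$lon, sp0$lat, stn[1], stn[2]) / v_t * 60))
    out <- pursuit_points(sp0$lon, sp0$lat, stn[1], stn[2], n_out)
    clon <- stn[1]; clat <- stn[2]
    lo <- list(); elapsed <- n_out
    repeat {
      ret_need <- gc_dist_nmi(clon, clat, sp1$lon, sp1$lat) / v_t * 60
      left <- dur - elapsed
      if (left <= ret_need + 30) break
      step <- min(sample(10:30, 1), floor(left - ret_need - 30))
      if (step < 1) break
      # tethered loiter: reposition toward the station when drifted off it
      p <- if (gc_dist_nmi(clon, clat, stn[1], stn[2]) > 6)
        leg_points(clon, clat, gc_bearing(clon, clat, stn[1], stn[2]),
                   runif(1, 2, 4), step)
      else wander_points(clon, clat, step, speed_lo = 0.2, speed_hi = 1.5)
      lo[[length(lo) + 1]] <- p
      clon <- p[step, 1]; clat <- p[step, 2]
      elapsed <- elapsed + step
    }
    lo <- if (length(lo)) do.call(rbind, lo) else
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lon", "lat")))
    inl <- pursuit_points(clon, clat, sp1$lon, sp1$lat, dur - elapsed)
    pts <- rbind(out, lo, inl)
    state <- c(rep("transit", n_out), rep("loiter", nrow(lo)),
               rep("transit", nrow(inl)))
  } else {
    # fishing: transit out, sinuous slow fishing legs, transit back
    v_t <- runif(1, 8, 12)
    brg <- if (!is.null(plan$ground_bearing)) plan$ground_bearing else runif(1, 0, 360)
    d_out <- min(80, max(15, v_t * dur / 60 * 0.18))
    n_out <- max(1L, ceiling(d_out / v_t * 60))
    ground <- gc_destination(sp0$lon, sp0$lat, brg, d_out)
    out <- pursuit_points(sp0$lon, sp0$lat, ground[1], ground[2], n_out)
    clon <- ground[1]; clat <- ground[2]
    heading <- runif(1, 0, 360)
    fish <- list(); fstate <- integer(0)
    elapsed <- n_out
    repeat {
      ret_need <- gc_dist_nmi(clon, clat, sp1$lon, sp1$lat) / v_t * 60
      left <- dur - elapsed
      if (left <= ret_need + 45) break
      leg_min <- min(sample(10:30, 1), floor(left - ret_need - 45))
      if (leg_min < 1) break
      v_f <- runif(1, 0.5, 5)
      # sinuous trawling: frequent course changes with occasional tow
      # reversals (doubling back along the grounds)
      turn <- if (runif(1) < 0.25) 180 + rnorm(1, 0, 30) else rnorm(1, 0, 60)
      heading <- (heading + turn) %% 360
      p <- leg_points(clon, clat, heading, v_f, leg_min)
      fish[[length(fish) + 1]] <- p
      clon <- p[leg_min, 1]; clat <- p[leg_min, 2]
      elapsed <- elapsed + leg_min
    }
    fish <- if (length(fish)) do.call(rbind, fish) else
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lon", "lat")))
    inl <- pursuit_points(clon, clat, sp1$lon, sp1$lat, dur - elapsed)
    pts <- rbind(out, fish, inl)
    state <- c(rep("transit", n_out), rep("fishing", nrow(fish)),
               rep("transit", nrow(inl)))
  }

  pts <- rbind(c(sp0$lon, sp0$lat), pts)   # minute 0 at the departure dock
  state <- c("dock", state)
  track <- data.frame(
    vessel_id = vessel_id,
    timestamp = t0 + 60 * (seq_len(nrow(pts)) - 1),
    lon = pts[, 1], lat = pts[, 2], state = state,
    stringsAsFactors = FALSE)
  legs <- gc_dist_nmi(track$lon[-nrow(track)], track$lat[-nrow(track)],
                      track$lon[-1], track$lat[-1])
  truth <- data.frame(
    vessel_id = vessel_id, behavior = behavior,
    true_start = t0, true_end = track$timestamp[nrow(track)],
    start_port = sp0$port_id, end_port = sp1$port_id,
    true_distance_nmi = sum(legs), stringsAsFactors = FALSE)
  list(truth = truth, track = track)
}

# slow random wander around a point (loitering tender)
wander_points <- function(lon, lat, n_min, speed_lo = 0.2, speed_hi = 1.5) {
  if (n_min <= 0) return(matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("lon", "lat"))))
  pts <- matrix(NA_real_, n_min, 2, dimnames = list(NULL, c("lon", "lat")))
  h <- runif(1, 0, 360)
  done <- 0
  while (done < n_min) {
    step <- min(sample(10:30, 1), n_min - done)
    h <- (h + rnorm(1, 0, 60)) %% 360
    p <- leg_points(lon, lat, h, runif(1, speed_lo, speed_hi), step)
    pts[(done + 1):(done + step), ] <- p
    lon <- p[step, 1]; lat <- p[step, 2]
    done <- done + step
  }
  pts
}

#' Sample VMS records from a continuous track
#'
#' Emits position records at the cadence of a [sampling_model()]: the first
#' fix at the first track minute, then successive intervals drawn as
#' nominal / jittered (35–60 min) / long gaps. Emitted records are exact
#' points of the 1-min track and carry only the fields a transponder sends.
#'
#' @param track A 1-min track (from [simulate_trip()] or a vessel history).
#' @param model A [sampling_model()].
#' @return Data frame with `vessel_id`, `timestamp`, `lat`, `lon`.
#' @export
sample_vms <- function(track, model = sampling_model()) {
  stopifnot(inherits(model, "sampling_model"))
  n <- nrow(track)
  idx <- 1L
  take <- integer(0)
  while (idx <= n) {
    take <- c(take, idx)
    u <- runif(1)
    iv <- if (u < model$long_gap_fraction) {
      if (length(model$gap_lengths_min) == 1) model$gap_lengths_min
      else sample(model$gap_lengths_min, 1, prob = model$gap_weights)
    } else if (u < model$long_gap_fraction + model$jitter_fraction_35_60) {
      sample(35:60, 1)
    } else model$nominal_interval_min
    idx <- idx + as.integer(iv)
  }
  data.frame(vessel_id = track$vessel_id[take],
             timestamp = track$timestamp[take],
             lat = track$lat[take], lon = track$lon[take],
             stringsAsFactors = FALSE)
}

#' Emit observer trip logs for truth trips
#'
#' Observers record dock-to-dock trip start/end times. Coverage selects each
#' trip independently; clock error perturbs recorded times. Two documented
#' inscription-error modes can be injected: `dock_extension_min` starts the
#' observed trip while the vessel is still tied up (observed trip too long)
#' and `late_start_min` starts it after the vessel is already under way
#' (observed trip too short).
#'
#' @param truth Truth-trip data frame ([simulate_trip()] rows).
#' @param coverage Probability a trip is observed, in \[0, 1\].
#' @param clock_sd_min SD (minutes) of independent normal clock error on
#'   start and end times.
#' @param dock_extension_min,late_start_min Deterministic start-time error
#'   modes, minutes (see above).
#' @return Data frame: `obs_trip_id`, `vessel_id`, `obs_start`, `obs_end`.
#' @export
emit_observer_records <- function(truth, coverage = 1, clock_sd_min = 0,
                                  dock_extension_min = 0, late_start_min = 0) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  keep <- runif(nrow(truth)) < coverage
  tr <- truth[keep, , drop = FALSE]
  if (!nrow(tr))
    return(data.frame(obs_trip_id = character(0), vessel_id = character(0),
                      obs_start = as.POSIXct(character(0), tz = "UTC"),
                      obs_end = as.POSIXct(character(0), tz = "UTC")))
  err_s <- rnorm(nrow(tr), 0, clock_sd_min) - dock_extension_min + late_start_min
  err_e <- rnorm(nrow(tr), 0, clock_sd_min)
  data.frame(
    obs_trip_id = sprintf("obs_%s_%03d", tr$vessel_id, seq_len(nrow(tr))),
    vessel_id = tr$vessel_id,
    obs_start = tr$true_start + 60 * err_s,
    obs_end = tr$true_end + 60 * err_e,
    stringsAsFactors = FALSE)
}

#' Emit fish tickets for fishing truth trips
#'
#' Each fishing trip lands once, producing a ticket whose date window spans
#' the fishing-start date through the landing date, whose port is the trip's
#' end port, and whose statistical areas are those its track crossed. An
#' error model can corrupt the human-recorded fields: swapped dates (landing
#' before fishing start) and blank ports.
#'
#' @param truth Truth-trip data frame.
#' @param records Position records used to derive crossed stat areas
#'   (typically the sampled VMS records); may be NULL.
#' @param areas Statistical-area polygons; may be NULL.
#' @param date_swap_prob,blank_port_prob Error-injection probabilities.
#' @return Fish-ticket data frame: `ticket_id`, `vessel_id`,
#'   `fishing_start_date`, `landing_date`, `port`, `gear`, `stat_areas`
#'   (semicolon-separated), `program`.
#' @export
emit_fish_tickets <- function(truth, records = NULL, areas = NULL,
                              date_swap_prob = 0, blank_port_prob = 0) {
  fi <- truth[truth$behavior %in% c("afa_fishing", "other_fishing"), , drop = FALSE]
  if (!nrow(fi))
    return(data.frame(ticket_id = character(0), vessel_id = character(0),
                      fishing_start_date = as.Date(character(0)),
                      landing_date = as.Date(character(0)),
                      port = character(0), gear = character(0),
                      stat_areas = character(0), program = character(0),
                      stringsAsFactors = FALSE))
  sa <- vapply(seq_len(nrow(fi)), function(i) {
    if (is.null(records) || is.null(areas)) return("")
    r <- records[records$vessel_id == fi$vessel_id[i] &
                   records$timestamp >= fi$true_start[i] &
                   records$timestamp <= fi$true_end[i], , drop = FALSE]
    ids <- unique(assign_stat_area(areas, r$lon, r$lat))
    paste(ids[!is.na(ids)], collapse = ";")
  }, character(1))
  out <- data.frame(
    ticket_id = sprintf("tk_%s_%03d", fi$vessel_id, seq_len(nrow(fi))),
    vessel_id = fi$vessel_id,
    fishing_start_date = as.Date(fi$true_start),
    landing_date = as.Date(fi$true_end),
    port = fi$end_port,
    gear = ifelse(fi$behavior == "afa_fishing", "pelagic_trawl", "bottom_trawl"),
    stat_areas = sa,
    program = ifelse(fi$behavior == "afa_fishing", "AFA", "other"),
    stringsAsFactors = FALSE)
  swap <- runif(nrow(out)) < date_swap_prob
  if (any(swap)) {
    tmp <- out$fishing_start_date[swap]
    # force a clearly incorrect window: landing precedes fishing start
    out$fishing_start_date[swap] <- out$landing_date[swap] + 2
    out$landing_date[swap] <- tmp - 2
  }
  out$port[runif(nrow(out)) < blank_port_prob] <- NA_character_
  out
}

#' Simulate a ground-truthed fleet
#'
#' One-stop generator: for each vessel, a history of dock dwells and trips
#' (behaviors drawn from `behavior_probs`; fishing trips last 1–4 days,
#' transits and tenders are shorter), a continuous 1-min track, VMS records
#' sampled under `sampling`, observer logs, and fish tickets. Vessels start
#' staggered across the year so winter "A", summer "B" and off-season trips
#' all occur.
#'
#' @param n_vessels Number of vessels.
#' @param trips_per_vessel Trips per vessel.
#' @param ports Port registry (default the two-hub `"bering_toy"` preset).
#' @param areas Statistical-area polygons (default [make_area_grid()]).
#' @param sampling A [sampling_model()]; use
#'   `sampling_model(jitter_fraction_35_60 = 0, long_gap_fraction = 0)` for
#'   gap-free streams.
#' @param behavior_probs Named probabilities over behaviors.
#' @param observer_coverage,observer_clock_sd_min Passed to
#'   [emit_observer_records()].
#' @param ticket_date_swap_prob Passed to [emit_fish_tickets()].
#' @param year Calendar year the fleet operates in.
#' @param seed Integer seed; all randomness flows from it.
#' @return List: `truth`, `records`, `observer`, `tickets`, `ports`, `areas`.
#' @export
simulate_fleet <- function(n_vessels = 5, trips_per_vessel = 4,
                           ports = build_port_registry("bering_toy"),
                           areas = make_area_grid(),
                           sampling = sampling_model(),
                           behavior_probs = c(afa_fishing = 0.45,
                                              other_fishing = 0.2,
                                              transit = 0.25, tender = 0.1),
                           observer_coverage = 1,
                           observer_clock_sd_min = 0,
                           ticket_date_swap_prob = 0,
                           year = 2013, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hubs <- ports$port_id[has_inport_constants(ports)]
  if (length(hubs) < 2) hubs <- ports$port_id[1:2]
  truth_all <- list(); rec_all <- list()
  starts <- sort(runif(n_vessels,
                       as.numeric(as.POSIXct(sprintf("%d-01-10", year), tz = "UTC")),
                       as.numeric(as.POSIXct(sprintf("%d-11-01", year), tz = "UTC"))))
  for (v in seq_len(n_vessels)) {
    vid <- sprintf("V%03d", v)
    t <- as.POSIXct(starts[v], tz = "UTC", origin = "1970-01-01")
    t <- trunc(t, "mins")
    tracks <- list()
    cur_port <- sample(hubs, 1)        # trips chain: next starts where last ended
    for (k in seq_len(trips_per_vessel)) {
      beh <- sample(names(behavior_probs), 1, prob = behavior_probs)
      p0 <- cur_port
      if (beh %in% c("afa_fishing", "other_fishing")) {
        p1 <- sample(hubs, 1)
        pr0 <- port_row(ports, p0); pr1 <- port_row(ports, p1)
        hop <- gc_dist_nmi(pr0$lon, pr0$lat, pr1$lon, pr1$lat)
        # 1-4 days of fishing, plus travel allowance when the ports differ
        dur <- round(runif(1, 1440, 5760) + hop / 10 * 60)
        # grounds lie toward the central shelf, not at a fixed compass point
        brg <- (gc_bearing(pr0$lon, pr0$lat, -165, 57) + runif(1, -30, 30)) %% 360
        plan <- list(behavior = beh, start_port = p0, end_port = p1,
                     duration_min = dur, ground_bearing = brg)
      } else if (beh == "transit") {
        p1 <- sample(setdiff(ports$port_id, p0), 1)
        d <- gc_dist_nmi(port_row(ports, p0)$lon, port_row(ports, p0)$lat,
                         port_row(ports, p1)$lon, port_row(ports, p1)$lat)
        dur <- round(d / runif(1, 8, 11) * 60)
        plan <- list(behavior = beh, start_port = p0, end_port = p1,
                     duration_min = max(dur, 60))
      } else {
        p1 <- p0
        plan <- list(behavior = beh, start_port = p0, end_port = p1,
                     duration_min = round(runif(1, 720, 2160)))
      }
      cur_port <- p1
      # dock dwell before departure keeps consecutive trips separable
      dwell <- round(runif(1, 240, 720))
      dock <- port_row(ports, plan$start_port)
      dwell_track <- data.frame(
        vessel_id = vid, timestamp = t + 60 * (0:(dwell - 1)),
        lon = dock$lon, lat = dock$lat, state = "dock",
        stringsAsFactors = FALSE)
      st <- simulate_trip(vid, plan, ports, t0 = t + 60 * dwell)
      tracks[[length(tracks) + 1]] <- dwell_track
      tracks[[length(tracks) + 1]] <- st$track
      truth_all[[length(truth_all) + 1]] <- st$truth
      t <- st$truth$true_end + 60
    }
    # trailing dwell so the final trip has an in-port tail
    dock <- tracks[[length(tracks)]]
    endp <- dock[nrow(dock), ]
    tail_track <- data.frame(
      vessel_id = vid, timestamp = endp$timestamp + 60 * (1:360),
      lon = endp$lon, lat = endp$lat, state = "dock", stringsAsFactors = FALSE)
    tracks[[length(tracks) + 1]] <- tail_track
    vt <- do.call(rbind, tracks)
    rec_all[[v]] <- sample_vms(vt, sampling)
  }
  truth <- do.call(rbind, truth_all)
  truth$trip_idx <- seq_len(nrow(truth))
  records <- do.call(rbind, rec_all)
  observer <- emit_observer_records(truth, coverage = observer_coverage,
                                    clock_sd_min = observer_clock_sd_min)
  tickets <- emit_fish_tickets(truth, records, areas,
                               date_swap_prob = ticket_date_swap_prob)
  # tender registrations: vessels working as tenders are known from
  # processor records, so each tender period is on a calendar
  td <- truth[truth$behavior == "tender", , drop = FALSE]
  tender_calendar <- data.frame(vessel_id = td$vessel_id,
                                start = td$true_start - 6 * 3600,
                                end = td$true_end + 6 * 3600,
                                stringsAsFactors = FALSE)
  list(truth = truth, records = records, observer = observer,
       tickets = tickets, tender_calendar = tender_calendar,
       ports = ports, areas = areas)
}
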