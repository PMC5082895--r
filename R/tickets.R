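split_areas <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Match fish tickets to trips
#'
#' A ticket matches a trip when the vessel ids agree and at least one trip
#' record lies in one of the ticket's statistical areas with a UTC date
#' inside the ticket's \[fishing start, landing\] window (dates inclusive;
#' tickets carry no clock time). Tickets whose landing date precedes their
#' fishing-start date are clearly incorrect and are excluded up front.
#' One trip may match many tickets (multi-day / multi-processor offloads);
#' when one ticket matches several trips, the trip with the most records
#' inside the ticket's areas and window wins, ties broken by proximity of
#' the trip's end time to the landing date.
#'
#' @param ts A `trip_set`.
#' @param tickets Fish-ticket data frame (see [emit_fish_tickets()]).
#' @return Data frame of `(trip_id, ticket_id)` pairs; excluded bad-date
#'   ticket ids are in attribute `"excluded_tickets"`.
#' @export
match_tickets <- function(ts, tickets) {
  pairs <- data.frame(trip_id = character(0), ticket_id = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(tickets) || !nrow(tickets)) {
    attr(pairs, "excluded_tickets") <- character(0)
    return(pairs)
  }
  bad <- tickets$landing_date < tickets$fishing_start_date
  excluded <- tickets$ticket_id[bad]
  tickets <- tickets[!bad, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tickets))) {
    tk <- tickets[i, ]
    cand <- ts$trips[ts$trips$vessel_id == tk$vessel_id, , drop = FALSE]
    if (!nrow(cand)) next
    areas <- split_areas(tk$stat_areas)
    score <- vapply(cand$trip_id, function(id) {
      r <- trip_records(ts, id)
      sum(!is.na(r$stat_area) & r$stat_area %in% areas &
            as.Date(r$timestamp) >= tk$fishing_start_date &
            as.Date(r$timestamp) <= tk$landing_date)
    }, numeric(1))
    hits <- which(score > 0)
    if (!length(hits)) next
    if (length(hits) > 1) {
      # resolve many-to-one: best area/window overlap, then end-time proximity
      best <- hits[score[hits] == max(score[hits])]
      if (length(best) > 1) {
        prox <- abs(as.numeric(difftime(as.Date(cand$end_time[best]),
                                        tk$landing_date, units = "days")))
        best <- best[which.min(prox)]
      }
      hits <- best[1]
    }
    out[[length(out) + 1]] <- data.frame(trip_id = cand$trip_id[hits],
                                         ticket_id = tk$ticket_id,
                                         stringsAsFactors = FALSE)
  }
  if (length(out)) pairs <- do.call(rbind, out)
  attr(pairs, "excluded_tickets") <- excluded
  pairs
}

#' Backfill missing trip ports from matched tickets
#'
#' When a transmission gap hides a trip's end-of-trip port visit, a matched
#' fish ticket names the landing port. The assignment is quality-checked:
#' the speeds implied by reaching the candidate port from the trip's final
#' record (and, when present, from the first record of the vessel's next
#' trip) must not exceed 14 kn; otherwise the port nearest the final record
#' is assigned instead. Start ports of immediately following trips are
#' backfilled symmetrically when they share the inferred visit.
#'
#' @param ts A `trip_set`.
#' @param tickets Fish tickets.
#' @param matches Pairs from [match_tickets()].
#' @param max_kn Speed ceiling for the feasibility check.
#' @return The `trip_set` with `end_port` (and `end_boundary = "ticket"` or
#'   `"nearest"`) filled for previously unknown ends.
#' @export
backfill_ports <- function(ts, tickets, matches, max_kn = 14) {
  ports <- attr(ts, "ports")
  todo <- which(is.na(ts$trips$end_port))
  for (i in todo) {
    tk_ids <- matches$ticket_id[matches$trip_id == ts$trips$trip_id[i]]
    if (!length(tk_ids)) next
    tk <- tickets[match(tk_ids[1], tickets$ticket_id), ]
    if (is.na(tk$port)) next
    last <- ts$records[ts$trips$end_row[i], ]
    cand <- port_row(ports, tk$port)
    d1 <- gc_dist_nmi(last$lon, last$lat, cand$lon, cand$lat)
    # flanking records: the trip's final fix and, when present, the
    # vessel's next fix on the far side of the gap
    nxt_i <- ts$trips$end_row[i] + 1L
    has_next <- nxt_i <= nrow(ts$records) &&
      ts$records$vessel_id[nxt_i] == last$vessel_id
    if (has_next) {
      nxt <- ts$records[nxt_i, ]
      gap_h <- as.numeric(difftime(nxt$timestamp, last$timestamp, units = "hours"))
      d2 <- gc_dist_nmi(nxt$lon, nxt$lat, cand$lon, cand$lat)
      # the visit lies somewhere inside the gap: both legs must fit at the cap
      ok <- gap_h > 0 && (d1 + d2) / gap_h <= max_kn
    } else {
      # no far-side fix: the vessel must reach the port by end of landing day
      land_h <- as.numeric(difftime(
        as.POSIXct(paste(tk$landing_date + 1, "00:00:00"), tz = "UTC"),
        last$timestamp, units = "hours"))
      ok <- land_h > 0 && d1 / land_h <= max_kn
    }
    if (ok) {
      ts$trips$end_port[i] <- tk$port
      ts$trips$end_boundary[i] <- "ticket"
    } else {
      np <- nearest_port(ports, last$lon, last$lat)
      ts$trips$end_port[i] <- np$port_id
      ts$trips$end_boundary[i] <- "nearest"
    }
  }
  ts
}

#' Partition fishing trips into AFA and non-AFA
#'
#' Trips labelled fishing are assigned to the AFA pollock program when
#' matched to an AFA-program ticket, and to the non-AFA class when matched
#' to any other ticket. Unmatched fishing trips follow the monthly rule: if
#' the vessel landed no AFA tickets in the trip's calendar month, the trip
#' is non-AFA; otherwise it is AFA when it falls inside a pollock season
#' ("A" or "B"), else non-AFA.
#'
#' @param ts A `trip_set` whose trips carry a `label` column with values
#'   `"fishing"` / `"nonfishing"` / `"unclassified"`.
#' @param tickets Fish tickets.
#' @param matches Pairs from [match_tickets()].
#' @param season_calendar See [trip_season()].
#' @return The `trip_set` with `label` refined to `afa_fishing` /
#'   `other_fishing` for fishing trips.
#' @export
partition_afa <- function(ts, tickets, matches,
                          season_calendar = default_season_calendar()) {
  if (!"label" %in% names(ts$trips)) stop("trips carry no label column")
  fi <- which(ts$trips$label == "fishing")
  for (i in fi) {
    tk_ids <- matches$ticket_id[matches$trip_id == ts$trips$trip_id[i]]
    if (length(tk_ids)) {
      prog <- tickets$program[match(tk_ids, tickets$ticket_id)]
      ts$trips$label[i] <- if (any(prog == "AFA")) "afa_fishing" else "other_fishing"
    } else {
      mon <- format(ts$trips$end_time[i], "%Y-%m")
      vtk <- tickets[tickets$vessel_id == ts$trips$vessel_id[i] &
                       format(as.Date(tickets$landing_date), "%Y-%m") == mon, ]
      if (!nrow(vtk) || !any(vtk$program == "AFA")) {
        ts$trips$label[i] <- "other_fishing"
      } else {
        seas <- trip_season(ts$trips$start_time[i], season_calendar)
        ts$trips$label[i] <- if (seas %in% c("A", "B")) "afa_fishing" else "other_fishing"
      }
    }
  }
  ts
}

#' Pollock season of a date
#'
#' The pollock fishery splits into a winter "A" season and a summer "B"
#' season; "N" marks dates outside both.
#'
#' @param time POSIXct or Date vector.
#' @param calendar List with `A` and `B` as `c(start, end)` month-day
#'   strings (`"%m-%d"`).
#' @return Character vector of `"A"`, `"B"`, `"N"`.
#' @export
trip_season <- function(time, calendar = default_season_calendar()) {
  md <- format(as.Date(time), "%m-%d")
  out <- rep("N", length(md))
  out[md >= calendar$A[1] & md <= calendar$A[2]] <- "A"
  out[md >= calendar$B[1] & md <= calendar$B[2]] <- "B"
  out
}

#' @rdname trip_season
#' @export
default_season_calendar <- function() {
  list(A = c("01-01", "06-09"), B = c("06-10", "10-31"))
}
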