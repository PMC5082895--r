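#' Remove duplicate VMS records
#'
#' Keeps at most one record per (vessel, timestamp) after sorting each
#' vessel's records by time. The first occurrence wins; duplicates at the
#' same timestamp but different positions are counted and reported via the
#' `"conflicts"` attribute.
#'
#' @param records Data frame with at least `vessel_id`, `timestamp`, `lat`,
#'   `lon`.
#' @return Deduplicated, time-sorted records.
#' @export
deduplicate <- function(records) {
  if (!nrow(records)) return(records)
  ord <- order(records$vessel_id, records$timestamp)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$vessel_id, format(records$timestamp, "%Y-%m-%d %H:%M:%S"))
  dup <- duplicated(key)
  # conflict = a dropped row whose position differs from the kept (first) row
  kept_pos <- paste(records$lat, records$lon)[match(key, key)]
  conflicts <- sum(dup & paste(records$lat, records$lon) != kept_pos)
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Derive per-record kinematic and geographic fields
#'
#' For each vessel's time-sorted records, computes the distance from the
#' previous record (`dist_prev_nmi`, great circle), the transmission
#' interval (`interval_min`), the implied speed (`speed_kn`), the nearest
#' port and distance to it, and the statistical-area membership
#' (point-in-polygon, boundary inclusive). The first record per vessel has
#' NA kinematics. Idempotent: re-deriving leaves the result unchanged.
#'
#' @param records Deduplicated, sorted records.
#' @param ports A port registry.
#' @param areas Statistical-area polygons, or NULL to skip area assignment.
#' @return Records with derived columns appended.
#' @export
derive_fields <- function(records, ports, areas = NULL) {
  if (!nrow(records)) {
    for (col in c("dist_prev_nmi", "interval_min", "speed_kn", "dist_port_nmi"))
      records[[col]] <- numeric(0)
    records$nearest_port <- character(0)
    records$stat_area <- character(0)
    return(records)
  }
  ord <- order(records$vessel_id, records$timestamp)
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  same_vessel <- c(FALSE, records$vessel_id[-1] == records$vessel_id[-n])
  d <- c(NA_real_, gc_dist_nmi(records$lon[-n], records$lat[-n],
                               records$lon[-1], records$lat[-1]))
  iv <- c(NA_real_, as.numeric(difftime(records$timestamp[-1],
                                        records$timestamp[-n], units = "mins")))
  d[!same_vessel] <- NA_real_
  iv[!same_vessel] <- NA_real_
  records$dist_prev_nmi <- d
  records$interval_min <- iv
  records$speed_kn <- ifelse(iv > 0, d / (iv / 60), NA_real_)
  np <- nearest_port(ports, records$lon, records$lat)
  records$nearest_port <- np$port_id
  records$dist_port_nmi <- np$dist_nmi
  records$stat_area <- if (is.null(areas)) NA_character_ else
    assign_stat_area(areas, records$lon, records$lat)
  rownames(records) <- NULL
  records
}

#' Remove records implying impossible speeds
#'
#' Fishing vessels rarely exceed ~12 kn, so records whose implied speed
#' from the previous kept record exceeds `max_kn` (default 14, a
#' conservative upper bound) are treated as position errors and removed.
#' Removal cascades: each vessel's stream is scanned forward, speeds are
#' recomputed against the last kept record, and the scan repeats until no
#' record exceeds the bound.
#'
#' @param records Records with derived fields ([derive_fields()]).
#' @param ports,areas Passed to [derive_fields()] for the final re-derivation.
#' @param max_kn Speed ceiling in knots.
#' @return Filtered records with derived fields recomputed; the number of
#'   removed records is in attribute `"removed"`.
#' @export
filter_speed <- function(records, ports, areas = NULL, max_kn = 14) {
  if (!nrow(records)) return(records)
  keep_all <- logical(0)
  parts <- split(seq_len(nrow(records)), records$vessel_id)
  drop_idx <- integer(0)
  for (idx in parts) {
    lon <- records$lon[idx]; lat <- records$lat[idx]
    tt <- as.numeric(records$timestamp[idx])
    keep <- rep(TRUE, length(idx))
    last <- 1L
    for (i in seq_along(idx)[-1]) {
      dt_h <- (tt[i] - tt[last]) / 3600
      v <- if (dt_h > 0) gc_dist_nmi(lon[last], lat[last], lon[i], lat[i]) / dt_h
           else Inf
      if (v > max_kn) keep[i] <- FALSE else last <- i
    }
    drop_idx <- c(drop_idx, idx[!keep])
  }
  out <- if (length(drop_idx)) records[-drop_idx, , drop = FALSE] else records
  out <- derive_fields(out, ports, areas)
  attr(out, "removed") <- length(drop_idx)
  out
}

#' Link VMS records to observer trips
#'
#' A record belongs to an observed trip when its timestamp falls within the
#' observer-recorded start and stop times (bounds inclusive) for the same
#' vessel. Observer intervals must not overlap within a vessel.
#'
#' @param records VMS records.
#' @param observer Observer trips: `obs_trip_id`, `vessel_id`, `obs_start`,
#'   `obs_end`.
#' @return Records with an `observed_trip_id` column (NA when unmatched).
#' @export
match_observer <- function(records, observer) {
  records$observed_trip_id <- NA_character_
  if (!nrow(records) || is.null(observer) || !nrow(observer)) return(records)
  for (v in unique(observer$vessel_id)) {
    ob <- observer[observer$vessel_id == v, , drop = FALSE]
    ob <- ob[order(ob$obs_start), , drop = FALSE]
    if (nrow(ob) > 1) {
      ovl <- which(ob$obs_start[-1] <= ob$obs_end[-nrow(ob)])
      if (length(ovl))
        stop("overlapping observer intervals for vessel ", v, ": ",
             paste(ob$obs_trip_id[c(ovl, ovl + 1)], collapse = ", "))
    }
    ri <- which(records$vessel_id == v)
    for (j in seq_len(nrow(ob))) {
      hit <- ri[records$timestamp[ri] >= ob$obs_start[j] &
                  records$timestamp[ri] <= ob$obs_end[j]]
      records$observed_trip_id[hit] <- ob$obs_trip_id[j]
    }
  }
  records
}

#' Run the full preprocessing stage
#'
#' Dedup, derive, speed-filter, and observer-match in the canonical order.
#'
#' @inheritParams filter_speed
#' @param observer Optional observer trips for [match_observer()].
#' @return Cleaned, enriched records.
#' @export
preprocess_vms <- function(records, ports, areas = NULL, observer = NULL,
                           max_kn = 14) {
  records <- deduplicate(records)
  records <- derive_fields(records, ports, areas)
  records <- filter_speed(records, ports, areas, max_kn = max_kn)
  match_observer(records, observer)
}
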