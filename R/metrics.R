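#' Linear extrapolation of a trip boundary to the dock
#'
#' Boundary in-port records usually sit some distance from the dock, so the
#' trajectory is extended to the point where distance from port is 0 nmi,
#' at the speed of the adjacent segment (floored to avoid unbounded added
#' time when the vessel was nearly stationary).
#'
#' @param dist_nmi Distance from port of the boundary record, nmi.
#' @param speed_kn Speed of the adjacent segment, knots.
#' @param floor_kn Minimum speed used for the time extrapolation.
#' @return List with `add_nmi` and `add_min`.
#' @export
extrapolate_to_port <- function(dist_nmi, speed_kn, floor_kn = 0.5) {
  if (is.na(dist_nmi) || dist_nmi <= 0) return(list(add_nmi = 0, add_min = 0))
  v <- max(if (is.na(speed_kn)) floor_kn else speed_kn, floor_kn)
  list(add_nmi = dist_nmi, add_min = dist_nmi / v * 60)
}

# one boundary's contribution: (trim_min, trim_nmi) measured span removed
# inside a hub buffer, plus (add_min, add_nmi) constants or extrapolation
boundary_adjustment <- function(ts, i, end, ports = attr(ts, "ports")) {
  port <- if (end) ts$trips$end_port[i] else ts$trips$start_port[i]
  none <- list(add_nmi = 0, add_min = 0, trim_nmi = 0, trim_min = 0,
               resolved = FALSE)
  if (is.na(port)) return(none)
  p <- port_row(ports, port)
  rows <- ts$trips$start_row[i]:ts$trips$end_row[i]
  r <- ts$records[rows, ]
  if (has_inport_constants(p)) {
    # hub: the in-port constants describe dock <-> 10-nmi threshold travel,
    # so the measured span is trimmed back to the threshold crossing and
    # the constants added in its place
    tm <- hub_trim(r, p, end)
    return(list(add_nmi = if (end) p$end_nmi else p$start_nmi,
                add_min = if (end) p$end_min else p$start_min,
                trim_nmi = tm$nmi, trim_min = tm$min, resolved = TRUE))
  }
  rec <- if (end) r[nrow(r), ] else r[1, ]
  d <- gc_dist_nmi(rec$lon, rec$lat, p$lon, p$lat)
  adj <- if (end) r$speed_kn[nrow(r)] else r$speed_kn[min(2, nrow(r))]
  ex <- extrapolate_to_port(d, adj)
  # a trip's clock starts at its first at-sea fix (the leading in-port
  # record anchors the port and the path, not the departure time), so the
  # leading in-port leg's time is not counted; its distance is real travel
  trim_min <- 0
  if (!end && nrow(r) > 1 &&
      identical(ts$trips$start_boundary[i], "in_port"))
    trim_min <- as.numeric(difftime(r$timestamp[2], r$timestamp[1],
                                    units = "mins"))
  list(add_nmi = ex$add_nmi, add_min = ex$add_min,
       trim_nmi = 0, trim_min = trim_min, resolved = TRUE)
}

# measured time/distance between a trip boundary and the hub radius
# crossing (linear interpolation on the crossing leg)
hub_trim <- function(r, p, end) {
  dp <- gc_dist_nmi(r$lon, r$lat, p$lon, p$lat)
  tt <- as.numeric(r$timestamp)
  n <- nrow(r)
  if (end) { r <- r[n:1, ]; dp <- dp[n:1]; tt <- tt[n:1] }
  if (dp[1] > p$radius_nmi) return(list(nmi = 0, min = 0))
  cross <- which(dp > p$radius_nmi)[1]
  if (is.na(cross)) return(list(nmi = 0, min = 0))   # trip never leaves buffer
  legs <- gc_dist_nmi(r$lon[1:(cross - 1)], r$lat[1:(cross - 1)],
                      r$lon[2:cross], r$lat[2:cross])
  iv <- abs(tt[2:cross] - tt[1:(cross - 1)]) / 60
  frac <- (p$radius_nmi - dp[cross - 1]) / (dp[cross] - dp[cross - 1])
  frac <- min(max(frac, 0), 1)
  list(nmi = sum(legs[-length(legs)]) + legs[length(legs)] * frac,
       min = sum(iv[-length(iv)]) + iv[length(iv)] * frac)
}

#' Compute trip durations and distances
#'
#' Duration is the time between a trip's first and last record plus the
#' boundary adjustments; distance is the sum of great-circle legs between
#' successive records plus the same adjustments. At hub ports the mean
#' in-port travel constants stand in for the dock-to-threshold portion:
#' the measured span is trimmed to the 10-nmi crossing and the constants
#' added. At other ports the trajectory is linearly extrapolated to the
#' dock. Trips with an open (unresolved) boundary are flagged as lower
#' bounds.
#'
#' @param ts A `trip_set` (ports are carried on the object).
#' @param constants Optional data frame (`port_id`, `start_nmi`,
#'   `start_min`, `end_nmi`, `end_min`) overriding the registry's in-port
#'   constants — typically the output of [estimate_inport_constants()].
#' @return The `trip_set` with `duration_min`, `distance_nmi` and
#'   `lower_bound` columns on `trips`.
#' @export
trip_metrics <- function(ts, constants = NULL) {
  ports <- attr(ts, "ports")
  if (!is.null(constants)) {
    j <- match(constants$port_id, ports$port_id)
    for (col in c("start_nmi", "start_min", "end_nmi", "end_min"))
      ports[[col]][j[!is.na(j)]] <- constants[[col]][!is.na(j)]
  }
  n <- nrow(ts$trips)
  dur <- dist <- numeric(n); lb <- logical(n)
  for (i in seq_len(n)) {
    rows <- ts$trips$start_row[i]:ts$trips$end_row[i]
    r <- ts$records[rows, ]
    base_min <- as.numeric(difftime(r$timestamp[nrow(r)], r$timestamp[1],
                                    units = "mins"))
    legs <- if (nrow(r) > 1)
      gc_dist_nmi(r$lon[-nrow(r)], r$lat[-nrow(r)], r$lon[-1], r$lat[-1])
    else 0
    a0 <- boundary_adjustment(ts, i, end = FALSE, ports = ports)
    a1 <- boundary_adjustment(ts, i, end = TRUE, ports = ports)
    dur[i] <- base_min - a0$trim_min - a1$trim_min + a0$add_min + a1$add_min
    dist[i] <- sum(legs) - a0$trim_nmi - a1$trim_nmi + a0$add_nmi + a1$add_nmi
    lb[i] <- !a0$resolved || !a1$resolved
  }
  ts$trips$duration_min <- dur
  ts$trips$distance_nmi <- dist
  ts$trips$lower_bound <- lb
  ts
}

#' @rdname trip_metrics
#' @param trip_id A trip id.
#' @return `trip_duration` / `trip_distance` return the single trip's
#'   metric in minutes / nautical miles.
#' @export
trip_duration <- function(ts, trip_id) {
  if (is.null(ts$trips$duration_min)) ts <- trip_metrics(ts)
  ts$trips$duration_min[match(trip_id, ts$trips$trip_id)]
}

#' @rdname trip_metrics
#' @export
trip_distance <- function(ts, trip_id) {
  if (is.null(ts$trips$distance_nmi)) ts <- trip_metrics(ts)
  ts$trips$distance_nmi[match(trip_id, ts$trips$trip_id)]
}

#' Estimate hub in-port travel constants
#'
#' For trips with contiguous transmissions (every interval at most
#' `max_interval_min`) between the dock and the port radius, measures the
#' distance travelled and time taken across the buffer, separately for
#' outbound (trip starts) and inbound (trip ends), interpolating linearly
#' at the radius crossing. Means over qualifying traversals become the
#' port's constants; with no qualifying traversal the registry defaults
#' are retained with a warning.
#'
#' @param ts A `trip_set`.
#' @param port_id Hub port to analyse.
#' @param radius_nmi Buffer radius (default: the port's registry radius).
#' @param max_interval_min Contiguity requirement between records.
#' @param dock_nmi A traversal qualifies only if it begins (ends) within
#'   this distance of the dock.
#' @return One-row data frame: `port_id`, `start_nmi`, `start_min`,
#'   `end_nmi`, `end_min`, `n_out`, `n_in`.
#' @export
estimate_inport_constants <- function(ts, port_id, radius_nmi = NULL,
                                      max_interval_min = 30, dock_nmi = 1) {
  ports <- attr(ts, "ports")
  p <- port_row(ports, port_id)
  if (is.null(radius_nmi)) radius_nmi <- p$radius_nmi
  outs <- list(); ins <- list()
  for (i in seq_len(nrow(ts$trips))) {
    rows <- ts$trips$start_row[i]:ts$trips$end_row[i]
    r <- ts$records[rows, ]
    dp <- gc_dist_nmi(r$lon, r$lat, p$lon, p$lat)
    if (identical(ts$trips$start_port[i], port_id)) {
      tr <- traverse_measure(r, dp, radius_nmi, max_interval_min, dock_nmi,
                             outbound = TRUE)
      if (!is.null(tr)) outs[[length(outs) + 1]] <- tr
    }
    if (identical(ts$trips$end_port[i], port_id)) {
      tr <- traverse_measure(r, dp, radius_nmi, max_interval_min, dock_nmi,
                             outbound = FALSE)
      if (!is.null(tr)) ins[[length(ins) + 1]] <- tr
    }
  }
  res <- data.frame(port_id = port_id,
                    start_nmi = p$start_nmi, start_min = p$start_min,
                    end_nmi = p$end_nmi, end_min = p$end_min,
                    n_out = length(outs), n_in = length(ins),
                    stringsAsFactors = FALSE)
  if (length(outs)) {
    m <- colMeans(do.call(rbind, outs))
    res$start_nmi <- m[1]; res$start_min <- m[2]
  }
  if (length(ins)) {
    m <- colMeans(do.call(rbind, ins))
    res$end_nmi <- m[1]; res$end_min <- m[2]
  }
  if (!length(outs) && !length(ins))
    warning("no qualifying traversals for ", port_id, "; defaults retained")
  res
}

# measure one dock-to-radius traversal (c(dist_nmi, dur_min)) or NULL
traverse_measure <- function(r, dp, radius_nmi, max_interval_min, dock_nmi,
                             outbound) {
  n <- nrow(r)
  if (n < 2) return(NULL)
  if (!outbound) {  # work on the reversed tail so both cases read forward
    r <- r[n:1, ]; dp <- dp[n:1]
  }
  if (dp[1] > dock_nmi) return(NULL)
  cross <- which(dp > radius_nmi)[1]
  if (is.na(cross) || cross < 2) return(NULL)
  iv <- abs(as.numeric(difftime(r$timestamp[2:cross], r$timestamp[1:(cross - 1)],
                                units = "mins")))
  if (any(iv > max_interval_min)) return(NULL)
  legs <- gc_dist_nmi(r$lon[1:(cross - 1)], r$lat[1:(cross - 1)],
                      r$lon[2:cross], r$lat[2:cross])
  # interpolate to the exact radius crossing on the final leg
  frac <- (radius_nmi - dp[cross - 1]) / (dp[cross] - dp[cross - 1])
  frac <- min(max(frac, 0), 1)
  d <- sum(legs[-length(legs)]) + legs[length(legs)] * frac
  t <- sum(iv[-length(iv)]) + iv[length(iv)] * frac
  c(d, t)
}

#' Measurement-error bound for trip durations
#'
#' With transmissions every `max_interval_min` minutes, a trip's estimated
#' start and end can each miss the true dock times by up to one interval
#' less a minute, so the duration error bound is twice the transmission
#' interval minus two minutes (58 min at the nominal 30-min rate).
#'
#' @param max_interval_min Transmission interval, minutes (at least 1).
#' @return The bound in minutes.
#' @examples
#' measurement_error_bound(30)  # 58
#' @export
measurement_error_bound <- function(max_interval_min) {
  if (any(max_interval_min < 1)) stop("interval must be at least 1 min")
  2 * max_interval_min - 2
}

#' Compare estimated trip durations with observer records
#'
#' Trips are paired with observed trips when at least one VMS record falls
#' inside the observed window (via the records' `observed_trip_id`), and
#' observed trips of `min_obs_duration` minutes or less are excluded.
#' Ambiguous pairings (one trip over several observed trips or vice versa)
#' are set aside. Signed percent error is positive when the VMS estimate
#' exceeds the observed duration; each pair's error bound uses the trip's
#' own largest transmission interval.
#'
#' @param ts A `trip_set` with metrics computed.
#' @param observer Observer trips.
#' @param min_obs_duration Exclusion threshold for short observed trips.
#' @param nominal_interval_min Interval assumed when a trip has a single
#'   record pair and no measurable gap.
#' @return List with `comparisons` (per pair: durations, `diff_min`,
#'   `pct_error`, `error_bound_min`, `within_bound`), `summary` (shares
#'   within bound / within 5% / their union, Spearman rho, aggregate and
#'   mean-absolute percent error) and `ambiguous` trip ids.
#' @export
compare_with_observer <- function(ts, observer, min_obs_duration = 200,
                                  nominal_interval_min = 30) {
  if (is.null(ts$trips$duration_min)) ts <- trip_metrics(ts)
  obs <- observer
  obs$obs_duration_min <- as.numeric(difftime(obs$obs_end, obs$obs_start,
                                              units = "mins"))
  obs <- obs[obs$obs_duration_min > min_obs_duration, , drop = FALSE]
  # trip -> set of observed ids its records fall in
  amb <- character(0)
  rowsets <- split(ts$records$observed_trip_id, ts$records$trip_id)
  pairs <- list()
  seen_obs <- list()
  for (tid in ts$trips$trip_id) {
    oids <- unique(stats::na.omit(rowsets[[tid]]))
    oids <- oids[oids %in% obs$obs_trip_id]
    if (!length(oids)) next
    if (length(oids) > 1) { amb <- c(amb, tid); next }
    seen_obs[[oids]] <- c(seen_obs[[oids]], tid)
    pairs[[length(pairs) + 1]] <- data.frame(trip_id = tid, obs_trip_id = oids,
                                             stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(list(comparisons = data.frame(), summary = list(n = 0),
                ambiguous = amb))
  pairs <- do.call(rbind, pairs)
  multi <- names(Filter(function(x) length(x) > 1, seen_obs))
  amb <- c(amb, unlist(seen_obs[multi], use.names = FALSE))
  pairs <- pairs[!pairs$obs_trip_id %in% multi, , drop = FALSE]
  ti <- match(pairs$trip_id, ts$trips$trip_id)
  oi <- match(pairs$obs_trip_id, obs$obs_trip_id)
  est <- ts$trips$duration_min[ti]
  ob <- obs$obs_duration_min[oi]
  max_iv <- ts$trips$max_gap_min[ti]
  max_iv[is.na(max_iv)] <- nominal_interval_min
  cmp <- data.frame(
    trip_id = pairs$trip_id, obs_trip_id = pairs$obs_trip_id,
    est_duration_min = est, obs_duration_min = ob,
    diff_min = est - ob,
    pct_error = (est - ob) / ob * 100,
    error_bound_min = measurement_error_bound(pmax(max_iv, 1)),
    stringsAsFactors = FALSE)
  cmp$within_bound <- abs(cmp$diff_min) <= cmp$error_bound_min
  summary <- list(
    n = nrow(cmp),
    share_within_bound = mean(cmp$within_bound),
    share_within_5pct = mean(abs(cmp$pct_error) <= 5),
    share_within_either = mean(cmp$within_bound | abs(cmp$pct_error) <= 5),
    spearman_rho = if (nrow(cmp) > 2)
      cor(cmp$est_duration_min, cmp$obs_duration_min, method = "spearman")
    else NA_real_,
    aggregate_pct_error = (sum(cmp$est_duration_min) - sum(cmp$obs_duration_min)) /
      sum(cmp$obs_duration_min) * 100,
    mean_abs_pct_error = mean(abs(cmp$pct_error)))
  list(comparisons = cmp, summary = summary, ambiguous = unique(amb))
}

#' Piecewise bias-correction regression for trip durations
#'
#' Trip-duration distributions are bimodal with a break near 700 min
#' (short non-fishing vs multi-day fishing trips), so bias in the estimates
#' is modelled separately on either side of the breakpoint: observed
#' log-duration regressed linearly on estimated log-duration within each
#' segment. Corrected durations and before/after error summaries let the
#' user accept or reject the correction.
#'
#' @param comparisons The `comparisons` data frame from
#'   [compare_with_observer()] (at least 50 pairs).
#' @param breakpoint_min Segment boundary on the estimated duration, min.
#' @return List: `models` (lm fits below/above, or NULL where degenerate),
#'   `corrected` (data frame with `corrected_duration_min`), and `summary`
#'   with aggregate percent error and trip-level mean absolute percent
#'   error before and after correction.
#' @export
bias_correction_regression <- function(comparisons, breakpoint_min = 700) {
  if (nrow(comparisons) < 50)
    stop("at least 50 comparison pairs are required")
  x <- log(comparisons$est_duration_min)
  y <- log(comparisons$obs_duration_min)
  lo <- comparisons$est_duration_min < breakpoint_min
  fit_side <- function(sel) {
    if (sum(sel) < 10 || sd(x[sel]) < 1e-8) return(NULL)
    lm(y ~ x, data = data.frame(x = x[sel], y = y[sel]))
  }
  m_lo <- fit_side(lo); m_hi <- fit_side(!lo)
  if (is.null(m_lo) && is.null(m_hi))
    warning("degenerate design; identity correction returned")
  corr <- comparisons$est_duration_min
  if (!is.null(m_lo) && any(lo))
    corr[lo] <- exp(predict(m_lo, data.frame(x = x[lo])))
  if (!is.null(m_hi) && any(!lo))
    corr[!lo] <- exp(predict(m_hi, data.frame(x = x[!lo])))
  out <- comparisons
  out$corrected_duration_min <- corr
  agg <- function(est) (sum(est) - sum(comparisons$obs_duration_min)) /
    sum(comparisons$obs_duration_min) * 100
  mae <- function(est) mean(abs((est - comparisons$obs_duration_min) /
                                  comparisons$obs_duration_min * 100))
  list(models = list(below = m_lo, above = m_hi), corrected = out,
       summary = list(breakpoint_min = breakpoint_min,
                      aggregate_pct_error_pre = agg(comparisons$est_duration_min),
                      aggregate_pct_error_post = agg(corr),
                      mean_abs_pct_error_pre = mae(comparisons$est_duration_min),
                      mean_abs_pct_error_post = mae(corr)))
}
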