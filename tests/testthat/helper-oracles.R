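# Independent oracles, kept free of the implementation paths they check.

# brute-force haversine on a 6371-km sphere, nmi
oracle_haversine_nmi <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a))) / 1852
}

# brute-force cascading speed filter on one vessel's records: repeatedly
# drop every record whose speed from its surviving predecessor exceeds the
# cap, recomputing from scratch each sweep, until stable
oracle_speed_filter <- function(df, max_kn = 14) {
  repeat {
    n <- nrow(df)
    if (n < 2) return(df)
    drop <- rep(FALSE, n)
    last <- 1
    for (i in 2:n) {
      dt_h <- as.numeric(difftime(df$timestamp[i], df$timestamp[last],
                                  units = "hours"))
      v <- oracle_haversine_nmi(df$lon[last], df$lat[last],
                                df$lon[i], df$lat[i]) / dt_h
      if (v > max_kn) drop[i] <- TRUE else last <- i
    }
    if (!any(drop)) return(df)
    df <- df[!drop, , drop = FALSE]
  }
}

# exact path length by independent haversine
oracle_path_nmi <- function(df) {
  n <- nrow(df)
  if (n < 2) return(0)
  sum(oracle_haversine_nmi(df$lon[-n], df$lat[-n], df$lon[-1], df$lat[-1]))
}

utc <- function(x) as.POSIXct(x, tz = "UTC")

# simple regular-interval record stream along given coordinates
records_from_coords <- function(lon, lat, vessel = "V1",
                                start = utc("2013-03-01 00:00:00"),
                                interval_min = 30) {
  data.frame(vessel_id = vessel,
             timestamp = start + 60 * interval_min * (seq_along(lon) - 1),
             lat = lat, lon = lon, stringsAsFactors = FALSE)
}
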