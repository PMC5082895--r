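#' Build a port registry
#'
#' A port registry indexes named landing locations, each with a detection
#' radius (the distance within which a position fix can be considered
#' "in port") and, for large protected-bay hub ports, mean in-port travel
#' constants used when computing trip durations and distances. Hub buffers
#' are capped at 10 nmi; smaller, exposed ports near fishing grounds use
#' tighter port-specific radii.
#'
#' @param x Either a preset name (currently `"bering_toy"`) or a data frame
#'   with columns `port_id`, `lat`, `lon`, `radius_nmi`, `region`
#'   (one of `"GOA"`, `"BS"`, `"AI"`, `"Other"`), and optionally the in-port
#'   constants `start_nmi`, `start_min`, `end_nmi`, `end_min` (NA when a port
#'   has none).
#' @return A `port_registry`: a validated data frame of ports supporting
#'   nearest-port queries via [nearest_port()].
#' @examples
#' ports <- build_port_registry("bering_toy")
#' nearest_port(ports, ports$lon[1], ports$lat[1])
#' @export
build_port_registry <- function(x = "bering_toy") {
  if (is.character(x) && length(x) == 1) x <- port_preset(x)
  stopifnot(is.data.frame(x))
  req <- c("port_id", "lat", "lon", "radius_nmi", "region")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("port table missing columns: ", paste(miss, collapse = ", "))
  for (col in c("start_nmi", "start_min", "end_nmi", "end_min"))
    if (is.null(x[[col]])) x[[col]] <- NA_real_
  if (nrow(x) < 2) stop("a port registry needs at least 2 ports")
  if (anyDuplicated(x$port_id)) stop("duplicate port_id: ",
    paste(unique(x$port_id[duplicated(x$port_id)]), collapse = ", "))
  if (any(x$lat < -90 | x$lat > 90 | x$lon < -180 | x$lon > 180))
    stop("port coordinates outside valid WGS84 ranges")
  if (any(x$radius_nmi <= 0 | x$radius_nmi > 10))
    stop("port radius_nmi must be in (0, 10]")
  x$region <- as.character(x$region)
  bad <- setdiff(unique(x$region), c("GOA", "BS", "AI", "Other"))
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  # warn on overlapping buffers: ambiguous in-port assignment territory
  if (nrow(x) >= 2) {
    for (i in seq_len(nrow(x) - 1)) {
      d <- gc_dist_nmi(x$lon[i], x$lat[i], x$lon[(i + 1):nrow(x)], x$lat[(i + 1):nrow(x)])
      ov <- which(d < x$radius_nmi[i] + x$radius_nmi[(i + 1):nrow(x)])
      for (j in ov)
        warning("port buffers overlap: ", x$port_id[i], " and ", x$port_id[i + j],
                call. = FALSE)
    }
  }
  x <- as.data.frame(x)
  rownames(x) <- NULL
  class(x) <- c("port_registry", "data.frame")
  x
}

#' @export
print.port_registry <- function(x, ...) {
  cat("<port_registry> ", nrow(x), " ports (",
      sum(has_inport_constants(x)), " with in-port constants)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

has_inport_constants <- function(ports) {
  !is.na(ports$start_nmi) & !is.na(ports$start_min) &
    !is.na(ports$end_nmi) & !is.na(ports$end_min)
}

# Two-hub layout echoing the Dutch Harbor / Akutan geometry: two protected
# 10-nmi hubs with in-port travel constants, plus small exposed ports with
# tight radii. Coordinates are approximate real port locations.
port_preset <- function(name) {
  switch(name,
    bering_toy = data.frame(
      port_id    = c("dutch_harbor", "akutan", "king_cove", "sand_point", "togiak"),
      lat        = c(53.89, 54.13, 55.06, 55.34, 59.06),
      lon        = c(-166.54, -165.78, -162.31, -160.50, -160.38),
      radius_nmi = c(10, 10, 3, 3, 3),
      region     = c("AI", "AI", "GOA", "GOA", "BS"),
      start_nmi  = c(10, 13, NA, NA, NA),
      start_min  = c(80, 101, NA, NA, NA),
      end_nmi    = c(10, 12, NA, NA, NA),
      end_min    = c(80, 92, NA, NA, NA),
      stringsAsFactors = FALSE
    ),
    stop("unknown port preset: ", name)
  )
}

#' Nearest port to a set of positions
#'
#' @param ports A [build_port_registry()] registry.
#' @param lon,lat Positions in decimal degrees (vectorised).
#' @return Data frame with `port_id` and `dist_nmi` per position.
#' @export
nearest_port <- function(ports, lon, lat) {
  stopifnot(inherits(ports, "port_registry"))
  n <- length(lon)
  if (n == 0) return(data.frame(port_id = character(0), dist_nmi = numeric(0)))
  # distance matrix: positions x ports (port count is small)
  d <- vapply(seq_len(nrow(ports)), function(j)
    gc_dist_nmi(lon, lat, ports$lon[j], ports$lat[j]), numeric(n))
  d <- matrix(d, nrow = n)
  j <- max.col(-d, ties.method = "first")
  data.frame(port_id = ports$port_id[j],
             dist_nmi = d[cbind(seq_len(n), j)],
             stringsAsFactors = FALSE)
}

port_row <- function(ports, id) {
  i <- match(id, ports$port_id)
  if (is.na(i)) stop("unknown port id: ", id)
  ports[i, , drop = FALSE]
}

#' Write / read a port registry as CSV
#' @param ports A port registry.
#' @param path File path.
#' @return `read_ports` returns a `port_registry`.
#' @export
write_ports <- function(ports, path) {
  utils::write.csv(as.data.frame(ports), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ports
#' @export
read_ports <- function(path) build_port_registry(utils::read.csv(path))
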