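#' Build a rectangular grid of statistical management areas
#'
#' State/federal statistical management areas are the polygons in which
#' landings are reported. For synthetic fleets we emulate them with a
#' regular lon/lat grid of rectangular cells, each carrying a numeric-style
#' area id. Any polygon set in the same long format (one row per vertex,
#' grouped by `area_id`, ring implicitly closed) works throughout the
#' package, so real area polygons can be substituted.
#'
#' @param lon_range,lat_range Extent of the grid, decimal degrees.
#' @param cell_deg Cell size: `c(lon, lat)` degrees.
#' @return A `stat_areas` data frame with columns `area_id`, `lon`, `lat`
#'   (polygon vertices in order).
#' @export
make_area_grid <- function(lon_range = c(-172, -158), lat_range = c(52, 60),
                           cell_deg = c(2, 1)) {
  lons <- seq(lon_range[1], lon_range[2] - cell_deg[1], by = cell_deg[1])
  lats <- seq(lat_range[1], lat_range[2] - cell_deg[2], by = cell_deg[2])
  rows <- list()
  k <- 0
  for (la in lats) for (lo in lons) {
    k <- k + 1
    rows[[k]] <- data.frame(
      area_id = sprintf("A%03d", k),
      lon = c(lo, lo + cell_deg[1], lo + cell_deg[1], lo),
      lat = c(la, la, la + cell_deg[2], la + cell_deg[2]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stat_areas", "data.frame")
  out
}

#' Assign positions to statistical areas
#'
#' Point-in-polygon assignment; points on a polygon boundary count as
#' inside (first matching area wins). Points outside every polygon get NA.
#'
#' @param areas A `stat_areas` polygon table (see [make_area_grid()]).
#' @param lon,lat Positions, decimal degrees (vectorised).
#' @return Character vector of area ids (NA where unassigned).
#' @export
assign_stat_area <- function(areas, lon, lat) {
  out <- rep(NA_character_, length(lon))
  if (length(lon) == 0 || is.null(areas)) return(out)
  todo <- seq_along(lon)
  for (id in unique(areas$area_id)) {
    if (!length(todo)) break
    ring <- areas[areas$area_id == id, ]
    hit <- sp::point.in.polygon(lon[todo], lat[todo], ring$lon, ring$lat) > 0
    out[todo[hit]] <- id
    todo <- todo[!hit]
  }
  out
}

#' Read / write polygon layers as GeoJSON
#'
#' Minimal GeoJSON interchange for polygon layers in the package's long
#' vertex format: a FeatureCollection of single-ring Polygons with an
#' `area_id` property.
#'
#' @param areas A `stat_areas` data frame.
#' @param path File path.
#' @return `read_areas_geojson` returns a `stat_areas` data frame.
#' @export
write_areas_geojson <- function(areas, path) {
  feats <- lapply(unique(areas$area_id), function(id) {
    ring <- areas[areas$area_id == id, ]
    coords <- cbind(ring$lon, ring$lat)
    coords <- rbind(coords, coords[1, ])  # close the ring
    list(type = "Feature",
         properties = list(area_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(coords)),
                                                   function(i) coords[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_areas_geojson
#' @export
read_areas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    m <- m[-nrow(m), , drop = FALSE]  # drop closing vertex
    data.frame(area_id = f$properties$area_id, lon = m[, 1], lat = m[, 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stat_areas", "data.frame")
  out
}
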