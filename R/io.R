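parse_utc <- function(x) as.POSIXct(x, tz = "UTC",
                                    tryFormats = c("%Y-%m-%d %H:%M:%S",
                                                   "%Y-%m-%dT%H:%M:%S",
                                                   "%Y-%m-%d %H:%M",
                                                   "%Y-%m-%d"))

#' Read and write the package's CSV interchange formats
#'
#' Timestamps are written and read as UTC `"%Y-%m-%d %H:%M:%S"`; dates as
#' ISO dates. Column layouts match the generators: VMS records
#' (`vessel_id`, `timestamp`, `lat`, `lon`), observer trips
#' (`obs_trip_id`, `vessel_id`, `obs_start`, `obs_end`), fish tickets
#' (see [emit_fish_tickets()]).
#'
#' @param path File path.
#' @param records,observer,tickets Data frames to write.
#' @return Readers return data frames with parsed time columns.
#' @export
read_vms <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- parse_utc(x$timestamp)
  x
}

#' @rdname read_vms
#' @export
write_vms <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_vms
#' @export
read_observer <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$obs_start <- parse_utc(x$obs_start)
  x$obs_end <- parse_utc(x$obs_end)
  x
}

#' @rdname read_vms
#' @export
write_observer <- function(observer, path) {
  out <- observer
  for (c in c("obs_start", "obs_end"))
    out[[c]] <- format(out[[c]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_vms
#' @export
read_tickets <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$fishing_start_date <- as.Date(x$fishing_start_date)
  x$landing_date <- as.Date(x$landing_date)
  x
}

#' @rdname read_vms
#' @export
write_tickets <- function(tickets, path) {
  utils::write.csv(tickets, path, row.names = FALSE)
  invisible(path)
}

#' Write a trip table (and record-to-trip mapping) as CSV
#'
#' @param ts A `trip_set`.
#' @param trips_path,mapping_path Output paths (`mapping_path` optional).
#' @return `trips_path`, invisibly.
#' @export
write_trips <- function(ts, trips_path, mapping_path = NULL) {
  out <- ts$trips
  for (c in c("start_time", "end_time"))
    out[[c]] <- format(out[[c]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, trips_path, row.names = FALSE)
  if (!is.null(mapping_path)) {
    map <- data.frame(vessel_id = ts$records$vessel_id,
                      timestamp = format(ts$records$timestamp,
                                         "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                      trip_id = ts$records$trip_id)
    utils::write.csv(map, mapping_path, row.names = FALSE)
  }
  invisible(trips_path)
}
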