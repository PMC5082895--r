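#' Default pipeline configuration
#'
#' Configuration for [run_pipeline()]: fleet size, sampling model
#' fractions, port rules, observer coverage, classification seed, gap-
#' simulation size, and per-stage toggles. Any subset can be overridden;
#' unknown names are rejected.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_vessels = 6, trips_per_vessel = 4,
    jitter_fraction_35_60 = 0.089, long_gap_fraction = 0.021,
    observer_coverage = 1, observer_clock_sd_min = 0,
    ticket_date_swap_prob = 0,
    speed_ceiling_kn = 2, min_dwell_min = 60, gap_bridge_max_min = 240,
    min_trip_records = 5, max_speed_kn = 14,
    gapsim_draws = 2000, run_gapsim = TRUE, run_classification = TRUE,
    year = 2013, seed = 1)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full trip-analysis pipeline on a synthetic fleet
#'
#' Orchestrates simulate, preprocess, segment, ticket-match, metrics,
#' observer comparison, classification and gap simulation under one seeded
#' configuration, writing artifacts and a summary report to `out_dir`.
#' Per-stage record counts are logged so every filter's data loss is
#' auditable. Deterministic for a fixed config.
#'
#' @param config A [pipeline_config()] (or a YAML file path of overrides).
#' @param out_dir Output directory (created if missing); NULL skips all
#'   file output.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every stage's outputs: `fleet`, `ts`
#'   (the final `trip_set`), `matches`, `comparison`, `gapsim`, `report`,
#'   and the stage `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  say <- function(stage, ...) {
    msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    log[[length(log) + 1]] <<- msg
    if (!quiet) message(msg)
  }

  say("simulate", "fleet: ", config$n_vessels, " vessels x ",
      config$trips_per_vessel, " trips, seed ", config$seed)
  fleet <- simulate_fleet(
    n_vessels = config$n_vessels, trips_per_vessel = config$trips_per_vessel,
    sampling = sampling_model(
      jitter_fraction_35_60 = config$jitter_fraction_35_60,
      long_gap_fraction = config$long_gap_fraction),
    observer_coverage = config$observer_coverage,
    observer_clock_sd_min = config$observer_clock_sd_min,
    ticket_date_swap_prob = config$ticket_date_swap_prob,
    year = config$year, seed = config$seed)
  say("simulate", nrow(fleet$truth), " truth trips, ",
      nrow(fleet$records), " VMS records")

  rec <- preprocess_vms(fleet$records, fleet$ports, fleet$areas,
                        observer = fleet$observer,
                        max_kn = config$max_speed_kn)
  say("preprocess", nrow(rec), " records after dedup + speed filter (",
      attr(rec, "removed") %||% 0, " removed)")

  rules <- port_rules(fleet$ports,
                      speed_ceiling_kn = config$speed_ceiling_kn,
                      min_dwell_min = config$min_dwell_min,
                      gap_bridge_max_min = config$gap_bridge_max_min)
  rec <- assign_port_status(rec, rules)
  ts <- segment_trips(rec, rules)
  say("segment", nrow(ts$trips), " raw trips")
  ts <- prune_short_trips(ts, min_records = config$min_trip_records)
  say("segment", nrow(ts$trips), " trips after pruning (",
      attr(ts$trips, "pruned"), " short trips removed)")

  matches <- match_tickets(ts, fleet$tickets)
  say("tickets", nrow(matches), " trip-ticket pairs; ",
      length(attr(matches, "excluded_tickets")), " bad-date tickets excluded")
  ts <- backfill_ports(ts, fleet$tickets, matches)
  # estimate hub in-port constants from contiguous traversals, then apply
  hubs <- fleet$ports$port_id[has_inport_constants(fleet$ports)]
  constants <- do.call(rbind, lapply(hubs, function(p)
    suppressWarnings(estimate_inport_constants(ts, p))))
  ts <- trip_metrics(ts, constants = constants)
  say("metrics", "durations and distances computed (in-port constants: ",
      paste(hubs, collapse = ", "), ")")

  comparison <- compare_with_observer(ts, fleet$observer)
  if (comparison$summary$n > 0)
    say("observer", sprintf(
      "%d pairs; %.1f%% within error bound; aggregate error %.2f%%",
      comparison$summary$n, 100 * comparison$summary$share_within_bound,
      comparison$summary$aggregate_pct_error))

  if (isTRUE(config$run_classification)) {
    fa <- fishing_area_default(fleet$areas)
    ts <- classify_trips(ts, fleet$tickets, matches, fishing_areas = fa,
                         tender_calendar = fleet$tender_calendar,
                         seed = config$seed)
    say("classify", "labels: ",
        paste(names(table(ts$trips$label)), table(ts$trips$label),
              sep = "=", collapse = ", "))
  }

  gapsim <- NULL
  if (isTRUE(config$run_gapsim)) {
    gapsim <- try(run_bias_experiment(ts, n_draws = config$gapsim_draws,
                                      seed = config$seed), silent = TRUE)
    if (inherits(gapsim, "try-error")) {
      say("gapsim", "skipped: no complete-transmission trips")
      gapsim <- NULL
    } else {
      say("gapsim", sprintf("mean reductions %% (k=1..4): %s",
                            paste(sprintf("%.2f", gapsim$summary$mean_pct),
                                  collapse = ", ")))
    }
  }

  report <- trip_report(ts)
  result <- list(fleet = fleet, records = rec, ts = ts, matches = matches,
                 comparison = comparison, gapsim = gapsim, report = report,
                 config = config, log = unlist(log))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vms(fleet$records, file.path(out_dir, "vms_records.csv"))
    write_ports(fleet$ports, file.path(out_dir, "ports.csv"))
    write_areas_geojson(fleet$areas, file.path(out_dir, "stat_areas.geojson"))
    write_observer(fleet$observer, file.path(out_dir, "observer.csv"))
    write_tickets(fleet$tickets, file.path(out_dir, "fish_tickets.csv"))
    write_trips(ts, file.path(out_dir, "trips.csv"),
                file.path(out_dir, "record_trip_map.csv"))
    utils::write.csv(report, file.path(out_dir, "trip_report.csv"),
                     row.names = FALSE)
    summary_json <- list(
      config = unclass(config),
      n_truth_trips = nrow(fleet$truth),
      n_trips = nrow(ts$trips),
      observer_comparison = comparison$summary,
      gapsim = if (!is.null(gapsim)) gapsim$summary else NULL)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(unlist(log), file.path(out_dir, "pipeline.log"))
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default fishing grounds for synthetic fleets: shelf cells north of the
# hub ports
fishing_area_default <- function(areas) {
  cent <- vapply(split(areas$lat, areas$area_id), mean, numeric(1))
  names(cent)[cent >= 54.5]
}

#' Trips by season, year and label
#'
#' The summary table of the pipeline report: counts of trips in each
#' season x year x label cell.
#'
#' @param ts A labelled `trip_set`.
#' @return Data frame with `year`, `season`, one column per label, and a
#'   `total`.
#' @export
trip_report <- function(ts) {
  if (!"label" %in% names(ts$trips)) ts$trips$label <- "unclassified"
  yr <- format(ts$trips$start_time, "%Y")
  se <- trip_season(ts$trips$start_time)
  tab <- table(paste(yr, se), ts$trips$label)
  out <- data.frame(year = sub(" .*", "", rownames(tab)),
                    season = sub(".* ", "", rownames(tab)),
                    stringsAsFactors = FALSE)
  for (l in colnames(tab)) out[[l]] <- as.integer(tab[, l])
  out$total <- as.integer(rowSums(tab))
  rownames(out) <- NULL
  out
}

#' Account recovered trips against ground truth
#'
#' Matches each truth trip to the recovered trips that overlap it in time
#' (same vessel), classifying every truth trip as `recovered` (exactly one
#' recovered trip, covering a majority of the truth interval and nothing
#' else's), `merged` (a recovered trip spans several truth trips), `split`
#' (several recovered trips inside one truth trip) or `missed`.
#'
#' @param ts A `trip_set`.
#' @param truth Truth-trip table from the generator.
#' @param slack_min Time slack when testing interval overlap.
#' @return List: `accounting` (per truth trip: status and matched trip
#'   ids), `one_to_one` share, and per-status counts.
#' @export
truth_recovery <- function(ts, truth, slack_min = 45) {
  status <- character(nrow(truth))
  match_ids <- character(nrow(truth))
  # recovered trip -> how many truth trips it overlaps
  t_over <- setNames(integer(nrow(ts$trips)), ts$trips$trip_id)
  overlaps <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- which(ts$trips$vessel_id == truth$vessel_id[i] &
                    ts$trips$start_time <= truth$true_end[i] + 60 * slack_min &
                    ts$trips$end_time >= truth$true_start[i] - 60 * slack_min)
    # require genuine interior overlap, not boundary grazing
    keep <- vapply(cand, function(j) {
      ov <- min(as.numeric(ts$trips$end_time[j]), as.numeric(truth$true_end[i])) -
        max(as.numeric(ts$trips$start_time[j]), as.numeric(truth$true_start[i]))
      ov > 0.2 * as.numeric(difftime(truth$true_end[i], truth$true_start[i],
                                     units = "secs"))
    }, logical(1))
    cand <- cand[keep]
    overlaps[[i]] <- cand
    t_over[cand] <- t_over[cand] + 1L
  }
  for (i in seq_len(nrow(truth))) {
    cand <- overlaps[[i]]
    if (!length(cand)) { status[i] <- "missed"; next }
    if (length(cand) > 1) { status[i] <- "split"
      match_ids[i] <- paste(ts$trips$trip_id[cand], collapse = ";"); next }
    if (t_over[cand] > 1) { status[i] <- "merged"
      match_ids[i] <- ts$trips$trip_id[cand]; next }
    status[i] <- "recovered"
    match_ids[i] <- ts$trips$trip_id[cand]
  }
  acc <- data.frame(truth[, c("vessel_id", "behavior", "true_start", "true_end")],
                    status = status, trip_id = match_ids,
                    stringsAsFactors = FALSE)
  list(accounting = acc,
       one_to_one = mean(status == "recovered"),
       counts = table(status))
}
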