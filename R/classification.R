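FEATURE_COLS <- c("avesp", "sddif", "avedif", "sdsp", "avgspstat")

#' Compute per-trip classification features
#'
#' Trip-level predictors for fishing vs non-fishing classification, each
#' computed on its own record subset:
#' \describe{
#'   \item{avesp, sdsp}{mean and SD of speed over records more than 10 nmi
#'     from port and moving (> 0 kn)}
#'   \item{sddif, avedif}{SD and mean of differences between speeds of
#'     consecutive records travelling at fishing speeds (0–5 kn)}
#'   \item{avgspstat}{mean speed over records inside designated fishing
#'     statistical areas}
#'   \item{duration}{trip duration in minutes (with boundary adjustments)}
#'   \item{start_region, end_region}{port region of the trip's start / end
#'     (GOA, BS, AI, Other; unknown ports fall in Other)}
#'   \item{season}{pollock season of the trip start (A, B, N)}
#' }
#' Features whose record subset is empty are NA and flagged.
#'
#' @param ts A `trip_set` with metrics computed.
#' @param fishing_areas Character vector of stat-area ids counted as
#'   fishing grounds (for `avgspstat`); NULL leaves it NA.
#' @param season_calendar See [trip_season()].
#' @return Data frame of features keyed by `trip_id`.
#' @export
compute_features <- function(ts, fishing_areas = NULL,
                             season_calendar = default_season_calendar()) {
  if (is.null(ts$trips$duration_min)) ts <- trip_metrics(ts)
  ports <- attr(ts, "ports")
  n <- nrow(ts$trips)
  out <- data.frame(trip_id = ts$trips$trip_id,
                    duration = ts$trips$duration_min,
                    avesp = NA_real_, sddif = NA_real_, avedif = NA_real_,
                    sdsp = NA_real_, avgspstat = NA_real_,
                    stringsAsFactors = FALSE)
  region_of <- function(port) {
    i <- match(port, ports$port_id)
    ifelse(is.na(i), "Other", ports$region[i])
  }
  out$start_region <- region_of(ts$trips$start_port)
  out$end_region <- region_of(ts$trips$end_port)
  out$season <- trip_season(ts$trips$start_time, season_calendar)
  for (i in seq_len(n)) {
    r <- ts$records[ts$trips$start_row[i]:ts$trips$end_row[i], ]
    sp <- r$speed_kn
    far <- !is.na(sp) & sp > 0 & r$dist_port_nmi > 10
    if (any(far)) {
      out$avesp[i] <- mean(sp[far])
      out$sdsp[i] <- if (sum(far) > 1) sd(sp[far]) else 0
    }
    slow <- which(!is.na(sp) & sp >= 0 & sp <= 5)
    if (length(slow) > 1) {
      d <- diff(sp[slow])
      out$avedif[i] <- mean(d)
      out$sddif[i] <- if (length(d) > 1) sd(d) else 0
    }
    if (!is.null(fishing_areas)) {
      ins <- !is.na(sp) & !is.na(r$stat_area) & r$stat_area %in% fishing_areas
      if (any(ins)) out$avgspstat[i] <- mean(sp[ins])
    }
  }
  for (col in FEATURE_COLS) out[[paste0(col, "_miss")]] <- as.numeric(is.na(out[[col]]))
  out
}

#' Rule-based trip labels
#'
#' The first classification tier: an ordered, configurable set of decision
#' rules (first match wins).
#' Defaults: a fish-ticket match makes a trip `fishing`; a trip whose
#' records all stay inside declared transit corridors or port radii is
#' `nonfishing`; a trip on a declared tender/charter calendar is
#' `nonfishing`; a trip with no fishing-speed records (0–5 kn) beyond
#' 10 nmi from port is `nonfishing`; anything else is `unclassified` and
#' falls through to the model tier.
#'
#' @param ts A `trip_set`.
#' @param matches Ticket matches from [match_tickets()].
#' @param corridors Optional corridor polygons.
#' @param tender_calendar Optional data frame (`vessel_id`, `start`, `end`
#'   POSIXct) of known tender/charter periods.
#' @return The `trip_set` with a `label` column:
#'   `fishing` / `nonfishing` / `unclassified`.
#' @export
apply_decision_rules <- function(ts, matches = NULL, corridors = NULL,
                                 tender_calendar = NULL) {
  ports <- attr(ts, "ports")
  lab <- rep("unclassified", nrow(ts$trips))
  matched <- if (!is.null(matches) && nrow(matches))
    ts$trips$trip_id %in% matches$trip_id else rep(FALSE, nrow(ts$trips))
  for (i in seq_len(nrow(ts$trips))) {
    if (matched[i]) { lab[i] <- "fishing"; next }
    r <- ts$records[ts$trips$start_row[i]:ts$trips$end_row[i], ]
    if (!is.null(corridors)) {
      in_cor <- !is.na(assign_stat_area(corridors, r$lon, r$lat))
      radius <- ports$radius_nmi[match(r$nearest_port, ports$port_id)]
      if (all(in_cor | r$dist_port_nmi <= radius)) { lab[i] <- "nonfishing"; next }
    }
    if (!is.null(tender_calendar)) {
      tc <- tender_calendar[tender_calendar$vessel_id == ts$trips$vessel_id[i], ]
      if (nrow(tc) && any(ts$trips$start_time[i] >= tc$start &
                            ts$trips$end_time[i] <= tc$end)) {
        lab[i] <- "nonfishing"; next
      }
    }
    slow_far <- !is.na(r$speed_kn) & r$speed_kn > 0 & r$speed_kn <= 5 &
      r$dist_port_nmi > 10
    if (!any(slow_far)) lab[i] <- "nonfishing"
  }
  ts$trips$label <- lab
  ts
}

# build the model frame: log duration, imputed features, factors
gam_frame <- function(features, medians = NULL) {
  df <- features
  df$ln_dur <- log(pmax(df$duration, 1))
  if (is.null(medians))
    medians <- vapply(FEATURE_COLS, function(c)
      median(df[[c]], na.rm = TRUE), numeric(1))
  for (c in FEATURE_COLS) {
    v <- df[[c]]
    v[is.na(v)] <- if (is.finite(medians[[c]])) medians[[c]] else 0
    df[[c]] <- v
  }
  df$season <- factor(df$season, levels = c("A", "B", "N"))
  df$start_region <- factor(df$start_region, levels = c("GOA", "BS", "AI", "Other"))
  df$end_region <- factor(df$end_region, levels = c("GOA", "BS", "AI", "Other"))
  attr(df, "medians") <- medians
  df
}

#' Fit the fishing-classification GAM
#'
#' Penalized-spline logistic model of the probability a trip is a fishing
#' trip: an isotropic bivariate smoother over (log duration, mean far-
#' from-port speed) — longer trips have more transit legs and hence higher
#' average speeds — univariate thin-plate smoothers over the speed
#' variability terms, and season and start/end-region factors. Trips
#' shorter than 200 min or longer than 15,000 min are excluded from
#' training as unrepresentative; factor terms collapse out automatically
#' when the training data hold a single level. Missing features are
#' imputed with training medians alongside missingness indicators.
#'
#' @param features Feature frame from [compute_features()].
#' @param labels Logical (or "fishing"/"nonfishing") vector aligned with
#'   `features`: TRUE for fishing.
#' @param split Training fraction (the rest is the held-out test set).
#' @param seed Seed for the train/test split.
#' @param threshold Probability at or above which a trip is labelled
#'   fishing.
#' @param duration_bounds Training-set duration limits, minutes.
#' @return A `vms_gam`: the mgcv fit plus imputation medians, threshold,
#'   training ranges, deviance explained and held-out accuracy.
#' @export
fit_gam <- function(features, labels, split = 0.75, seed = NULL,
                    threshold = 0.5, duration_bounds = c(200, 15000)) {
  if (is.character(labels)) labels <- labels == "fishing"
  stopifnot(length(labels) == nrow(features))
  keep <- !is.na(labels) & features$duration > duration_bounds[1] &
    features$duration < duration_bounds[2]
  df <- gam_frame(features[keep, , drop = FALSE])
  y <- labels[keep]
  if (length(unique(y)) < 2) stop("both classes required to fit the model")
  if (sum(keep) < 20) stop("too few labelled trips to fit the model")
  if (!is.null(seed)) set.seed(seed)
  tr <- sample(seq_len(nrow(df)), size = floor(split * nrow(df)))
  te <- setdiff(seq_len(nrow(df)), tr)
  dtr <- df[tr, , drop = FALSE]; ytr <- y[tr]
  terms <- c(smooth_term(c("ln_dur", "avesp"), dtr, k_max = 25),
             smooth_term("sddif", dtr), smooth_term("sdsp", dtr))
  for (f in c("season", "start_region", "end_region"))
    if (nlevels(droplevels(dtr[[f]])) >= 2) terms <- c(terms, f)
  for (c in c("avesp", "sddif", "sdsp")) {
    mc <- paste0(c, "_miss")
    if (length(unique(dtr[[mc]])) > 1) terms <- c(terms, mc)
  }
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  dtr$y <- as.numeric(ytr)
  fit <- mgcv::gam(form, family = stats::binomial(), data = dtr)
  medians <- attr(df, "medians")
  dte <- df[te, , drop = FALSE]
  acc <- NA_real_
  if (length(te)) {
    p <- as.numeric(predict(fit, newdata = dte, type = "response"))
    acc <- mean((p >= threshold) == y[te])
  }
  ranges <- lapply(df[c("ln_dur", FEATURE_COLS)], range)
  structure(list(model = fit, threshold = threshold, medians = medians,
                 terms = terms, train_ranges = ranges,
                 deviance_explained = summary(fit)$dev.expl,
                 holdout_accuracy = acc, n_train = length(tr),
                 n_test = length(te)),
            class = "vms_gam")
}

# spline term sized to the available unique values; linear fallback
smooth_term <- function(vars, data, k_max = 10) {
  nu <- min(vapply(vars, function(v) length(unique(data[[v]])), numeric(1)))
  if (nu < 4) return(vars[length(vars)])       # too few values: linear term
  k <- min(k_max, nu - 1)
  sprintf("s(%s, k = %d)", paste(vars, collapse = ", "), k)
}

#' @export
print.vms_gam <- function(x, ...) {
  cat("<vms_gam> logistic fishing-trip classifier\n",
      "  terms: ", paste(x$terms, collapse = " + "), "\n",
      sprintf("  deviance explained: %.1f%%; held-out accuracy: %.1f%% (n = %d)\n",
              100 * x$deviance_explained, 100 * x$holdout_accuracy, x$n_test),
      sep = "")
  invisible(x)
}

#' Predict fishing probability for trips
#'
#' @param model A `vms_gam` from [fit_gam()].
#' @param features Feature frame from [compute_features()].
#' @return Data frame: `trip_id`, `p_fishing`, `label` (fishing at or above
#'   the model threshold), and `extrapolated` when any feature lies outside
#'   its training range.
#' @export
predict_fishing <- function(model, features) {
  stopifnot(inherits(model, "vms_gam"))
  if (!nrow(features)) stop("empty feature set")
  df <- gam_frame(features, medians = model$medians)
  p <- as.numeric(predict(model$model, newdata = df, type = "response"))
  extra <- rep(FALSE, nrow(df))
  for (v in names(model$train_ranges)) {
    rg <- model$train_ranges[[v]]
    extra <- extra | df[[v]] < rg[1] | df[[v]] > rg[2]
  }
  data.frame(trip_id = features$trip_id, p_fishing = p,
             label = ifelse(p >= model$threshold, "fishing", "nonfishing"),
             extrapolated = extra, stringsAsFactors = FALSE)
}

#' Full classification tier: rules, model, AFA partition
#'
#' Applies the decision rules, fits the GAM on rule-labelled trips, scores
#' the remaining unclassified trips, then partitions fishing trips into
#' AFA and non-AFA via their tickets and the monthly rule.
#'
#' @param ts A `trip_set` with metrics.
#' @param tickets,matches Tickets and [match_tickets()] pairs.
#' @param fishing_areas Stat areas counted as fishing grounds.
#' @param corridors,tender_calendar Passed to [apply_decision_rules()].
#' @param seed Train/test split seed.
#' @return The `trip_set` with final labels (`afa_fishing`,
#'   `other_fishing`, `nonfishing`, or `unclassified` if the model tier
#'   could not run); the fitted model is in attribute `"gam"`.
#' @export
classify_trips <- function(ts, tickets, matches, fishing_areas = NULL,
                           corridors = NULL, tender_calendar = NULL,
                           seed = NULL) {
  ts <- apply_decision_rules(ts, matches, corridors, tender_calendar)
  feats <- compute_features(ts, fishing_areas)
  unc <- ts$trips$label == "unclassified"
  model <- NULL
  if (any(unc)) {
    lab <- ts$trips$label[!unc]
    fit_ok <- length(unique(lab)) == 2 && sum(!unc) >= 20
    if (fit_ok) {
      model <- try(fit_gam(feats[!unc, , drop = FALSE], lab == "fishing",
                           seed = seed), silent = TRUE)
      if (!inherits(model, "vms_gam")) model <- NULL
    }
    if (!is.null(model)) {
      pred <- predict_fishing(model, feats[unc, , drop = FALSE])
      ts$trips$label[unc] <- pred$label
    }
  }
  ts <- partition_afa(ts, tickets, matches)
  attr(ts, "gam") <- model
  ts
}
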