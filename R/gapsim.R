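#' Select trips with complete, regular transmissions
#'
#' The record-removal experiment needs trips free of pre-existing gaps, so
#' only trips whose every transmission interval lies inside
#' `interval_range` qualify.
#'
#' @param ts A `trip_set`.
#' @param interval_range Allowed interval range in minutes.
#' @param min_records Minimum records a trip must have to be usable.
#' @return Character vector of qualifying trip ids.
#' @export
select_complete_trips <- function(ts, interval_range = c(25, 35),
                                  min_records = 7) {
  ok <- vapply(seq_len(nrow(ts$trips)), function(i) {
    rows <- ts$trips$start_row[i]:ts$trips$end_row[i]
    if (length(rows) < min_records) return(FALSE)
    iv <- as.numeric(difftime(ts$records$timestamp[rows[-1]],
                              ts$records$timestamp[rows[-length(rows)]],
                              units = "mins"))
    all(iv >= interval_range[1] & iv <= interval_range[2])
  }, logical(1))
  ts$trips$trip_id[ok]
}

#' Remove consecutive records to simulate a transmission gap
#'
#' Removing k consecutive records from a stream of 30-min transmissions
#' produces a single gap of (k+1) x 30 min. The first removal happens at
#' `position`; subsequent removals take the records one, two, or three
#' positions prior, so the removed block is `position - k + 1` through
#' `position`. At least one record must remain on each side.
#'
#' @param records A trip's records (time-ordered data frame).
#' @param k Number of consecutive records to remove (1–4).
#' @param position Index of the first-removed record.
#' @return The degraded records.
#' @export
remove_records <- function(records, k, position) {
  n <- nrow(records)
  if (!(k %in% 1:4)) stop("k must be between 1 and 4")
  if (position - k + 1 < 2 || position > n - 1)
    stop("trip too short for this removal (need a record on each side)")
  records[-((position - k + 1):position), , drop = FALSE]
}

#' Over-water path length of a record sequence
#' @param records Data frame with `lon`, `lat` in time order.
#' @return Sum of great-circle legs, nmi.
#' @export
path_length_nmi <- function(records) {
  n <- nrow(records)
  if (n < 2) return(0)
  sum(gc_dist_nmi(records$lon[-n], records$lat[-n],
                  records$lon[-1], records$lat[-1]))
}

#' Record-removal bias experiment
#'
#' Quantifies how transmission gaps shorten estimated trip distances.
#' Trips with complete 25–35-min transmissions are sampled with
#' replacement; per draw a removal position is chosen uniformly (valid for
#' every k in `k_set`) and, for each k, the percent reduction in
#' over-water path length, (full − gapped) / full × 100, is recorded.
#' Straightening can only shorten a polyline, so every draw's reduction is
#' nonnegative and grows with k. In-port constants are excluded from the
#' path length: they are unaffected by gaps.
#'
#' @param ts A `trip_set`.
#' @param n_draws Number of Monte-Carlo draws.
#' @param k_set Gap sizes (records removed) to simulate.
#' @param interval_range Complete-trip interval window, minutes.
#' @param seed Optional RNG seed.
#' @return A `gap_sim` list: `summary` (per k: `gap_min`, mean, MAD,
#'   quartiles, outlier count beyond 1.5 x the upper quartile), `draws`
#'   (long table, boxplot-ready), `max_gap_ecdf` (ECDF of each input
#'   trip's largest interval), `eligible` trip ids, `n_draws`, `seed`.
#' @export
run_bias_experiment <- function(ts, n_draws = 5000, k_set = 1:4,
                                interval_range = c(25, 35), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  max_k <- max(k_set)
  elig <- select_complete_trips(ts, interval_range,
                                min_records = max_k + 3)
  if (!length(elig)) stop("no trips with complete transmissions")
  # cache per-trip leg lengths once
  cache <- lapply(elig, function(id) {
    r <- trip_records(ts, id)
    legs <- gc_dist_nmi(r$lon[-nrow(r)], r$lat[-nrow(r)], r$lon[-1], r$lat[-1])
    list(lon = r$lon, lat = r$lat, legs = legs, total = sum(legs))
  })
  names(cache) <- elig
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(k_set),
                  dimnames = list(NULL, paste0("k", k_set)))
  pick <- sample(seq_along(elig), n_draws, replace = TRUE)
  for (d in seq_len(n_draws)) {
    tr <- cache[[pick[d]]]
    n <- length(tr$lon)
    p <- sample((max_k + 1):(n - 1), 1)      # first removal; block extends back
    for (ki in seq_along(k_set)) {
      k <- k_set[ki]
      a <- p - k                              # last kept before the gap
      b <- p + 1                              # first kept after the gap
      bridged <- gc_dist_nmi(tr$lon[a], tr$lat[a], tr$lon[b], tr$lat[b])
      removed <- sum(tr$legs[a:(b - 1)])
      draws[d, ki] <- (removed - bridged) / tr$total * 100
    }
  }
  summ <- do.call(rbind, lapply(seq_along(k_set), function(ki) {
    x <- draws[, ki]
    q <- quantile(x, c(0.25, 0.5, 0.75))
    data.frame(k_removed = k_set[ki],
               gap_min = (k_set[ki] + 1) * 30,
               mean_pct = mean(x), mad_pct = mean(abs(x - mean(x))),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]],
               n_outliers = sum(x > 1.5 * q[[3]]),
               n_draws = n_draws)
  }))
  max_gaps <- ts$trips$max_gap_min[!is.na(ts$trips$max_gap_min)]
  structure(list(summary = summ,
                 draws = data.frame(k_removed = rep(k_set, each = n_draws),
                                    pct_reduction = as.vector(draws)),
                 max_gap_ecdf = if (length(max_gaps)) ecdf(max_gaps) else NULL,
                 eligible = elig, n_draws = n_draws, seed = seed),
            class = "gap_sim")
}

#' @export
print.gap_sim <- function(x, ...) {
  cat("<gap_sim> ", x$n_draws, " draws over ", length(x$eligible),
      " complete trips\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Exhaustive mean reduction for one trip (enumeration oracle companion)
#'
#' Exact mean percent reduction over every valid removal position for a
#' given k — the closed-form counterpart the Monte-Carlo experiment
#' converges to on a single trip.
#'
#' @param records A trip's records.
#' @param k Records removed.
#' @param positions_as Validity convention: positions valid for `max_k`
#'   (matching [run_bias_experiment()]'s shared-position draws).
#' @return Mean percent reduction over all valid positions.
#' @export
exhaustive_mean_reduction <- function(records, k, positions_as = k) {
  n <- nrow(records)
  total <- path_length_nmi(records)
  ps <- (positions_as + 1):(n - 1)
  red <- vapply(ps, function(p) {
    deg <- remove_records(records, k, p)
    (total - path_length_nmi(deg)) / total * 100
  }, numeric(1))
  mean(red)
}
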