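#' Segment colony-based foraging trips from a fix series
#'
#' A foraging trip is a maximal run of fixes farther than `buffer_km` from
#' the colony, extended to the bounding buffer-crossing fixes on either side
#' (when present), i.e. the last fix inside the buffer before departure and
#' the first fix inside after return. Runs spanning less than
#' `min_duration_h` are discarded. Trips are disjoint and time-ordered; a
#' series that never leaves the buffer yields an empty list.
#'
#' @param series Fix data frame for one individual (columns `id`,
#'   `timestamp`, `lon`, `lat`, `speed_kmh`), e.g. one element of
#'   [read_fixes()] or one individual of [simulate_tracks()].
#' @param mask A [landscape_mask()] (supplies the colony position).
#' @param buffer_km Colony buffer radius (km). The shortest reported trips
#'   last about half an hour, so the defaults keep brief beach excursions
#'   out while retaining genuine short trips.
#' @param min_duration_h Minimum trip duration (h).
#' @return List of `forage_trip` objects.
#' @export
segment_trips <- function(series, mask, buffer_km = 0.5,
                          min_duration_h = 0.5) {
  stopifnot(buffer_km > 0, min_duration_h >= 0)
  if (length(unique(series$id)) > 1L)
    stop("segment_trips expects fixes from a single individual; split first")
  if (is.unsorted(series$timestamp, strictly = TRUE))
    stop("fix series must have strictly increasing timestamps")
  n <- nrow(series)
  d <- colony_distance_km(mask, series$lon, series$lat)
  outside <- d > buffer_km
  if (!any(outside)) return(list())

  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trips <- list()
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    complete <- s > 1L && e < n
    s_ext <- max(1L, s - 1L)
    e_ext <- min(n, e + 1L)
    dur <- as.numeric(difftime(series$timestamp[e_ext],
                               series$timestamp[s_ext], units = "hours"))
    if (dur < min_duration_h) next
    fixes <- series[s_ext:e_ext, , drop = FALSE]
    rownames(fixes) <- NULL
    trips[[length(trips) + 1L]] <- structure(
      list(individual = series$id[1], fixes = fixes,
           start = fixes$timestamp[1], end = fixes$timestamp[nrow(fixes)],
           complete = complete, colony = mask$colony),
      class = "forage_trip")
  }
  trips
}

#' @export
print.forage_trip <- function(x, ...) {
  cat(sprintf("Foraging trip: %s, %s -> %s (%s, %d fixes)\n",
              x$individual, format(x$start, "%Y-%m-%d %H:%M"),
              format(x$end, "%Y-%m-%d %H:%M"),
              if (x$complete) "complete" else "incomplete",
              nrow(x$fixes)))
  invisible(x)
}

map_dest_class <- function(cls) {
  ifelse(cls %in% c("sea", "tidal_flat"), "sea",
         ifelse(cls == "mainland", "inland",
                ifelse(cls == "island", "island", NA_character_)))
}

#' Classify the destination of a trip
#'
#' Dwell fixes (device speed below `dwell_speed`, outside the colony buffer)
#' are classified by the mask; tidal-flat dwell counts to the marine side.
#' A trip is `"sea"` or `"inland"` when dwell lies (almost) wholly over one
#' side, `"mixed"` when the marine and mainland sides each hold at least
#' `mixed_min_share` of dwell fixes, and `"island"` when dwell occurs only
#' on islands. With no dwell fixes at all, the class of the most distant fix
#' decides.
#'
#' @param trip A `forage_trip`.
#' @param mask A [landscape_mask()].
#' @param dwell_speed Speed threshold separating dwelling from flight
#'   (km/h); the terrestrial feeding filter value is reused.
#' @param mixed_min_share Minimum share per side to call a trip mixed.
#' @return One of `"sea"`, `"inland"`, `"mixed"`, `"island"`.
#' @export
classify_destination <- function(trip, mask, dwell_speed = 10,
                                 mixed_min_share = 0.1) {
  f <- trip$fixes
  cls <- classify_points(mask, f$lon, f$lat, use_colony = TRUE)
  dwell <- f$speed_kmh < dwell_speed & cls != "colony"
  if (!any(dwell)) {
    d <- colony_distance_km(mask, f$lon, f$lat)
    far <- which.max(d)
    out <- map_dest_class(cls[far])
    return(if (is.na(out)) "sea" else out)
  }
  dc <- cls[dwell]
  p_marine <- mean(dc %in% c("sea", "tidal_flat"))
  p_land <- mean(dc == "mainland")
  p_island <- mean(dc == "island")
  if (p_marine >= mixed_min_share && p_land >= mixed_min_share) return("mixed")
  if (p_island == 1) return("island")
  c("sea", "inland", "island")[which.max(c(p_marine, p_land, p_island))]
}

#' Trip metrics: duration, range, distance, straightness, destination
#'
#' Foraging range is the maximum great-circle distance from the colony to
#' any fix; total distance is the sum of successive great-circle legs; the
#' straightness index is `2 * range / total`, reaching 1 for a perfectly
#' direct out-and-back flight (capped at 1 for complete trips, where
#' interpolation noise can nudge it above).
#'
#' @param trip A `forage_trip` with at least two fixes.
#' @param mask A [landscape_mask()].
#' @param dwell_speed,mixed_min_share Passed to [classify_destination()].
#' @return One-row data frame of metrics.
#' @export
trip_metrics <- function(trip, mask, dwell_speed = 10,
                         mixed_min_share = 0.1) {
  f <- trip$fixes
  if (nrow(f) < 2L) stop("degenerate trip: fewer than 2 fixes")
  duration <- as.numeric(difftime(trip$end, trip$start, units = "hours"))
  rng <- max(colony_distance_km(mask, f$lon, f$lat))
  total <- sum(gc_dist_km(f$lon[-nrow(f)], f$lat[-nrow(f)],
                          f$lon[-1], f$lat[-1]))
  straight <- 2 * rng / total
  if (trip$complete) straight <- min(1, straight)
  data.frame(individual = trip$individual, start = trip$start,
             end = trip$end, complete = trip$complete,
             duration_h = duration, foraging_range_km = rng,
             total_distance_km = total, straightness = straight,
             destination = classify_destination(trip, mask, dwell_speed,
                                                mixed_min_share),
             stringsAsFactors = FALSE)
}

#' Metrics table for a collection of trips
#'
#' @param trips List of `forage_trip` objects (possibly from several
#'   individuals, concatenated).
#' @param mask A [landscape_mask()].
#' @param ... Passed to [trip_metrics()].
#' @return Data frame, one row per trip, with a `trip` index per individual.
#' @export
trips_table <- function(trips, mask, ...) {
  if (!length(trips)) stop("no trips supplied")
  tt <- do.call(rbind, lapply(trips, trip_metrics, mask = mask, ...))
  tt <- tt[order(tt$individual, tt$start), ]
  tt$trip <- stats::ave(seq_len(nrow(tt)), tt$individual,
                        FUN = seq_along)
  rownames(tt) <- NULL
  tt[, c("individual", "trip", setdiff(names(tt), c("individual", "trip")))]
}

#' Summarise trip metrics by destination class
#'
#' @param tt Trip metrics table from [trips_table()].
#' @return Data frame with one row per destination class plus an overall
#'   row: trip count, percentage of all trips, and mean/SE/min/max of
#'   duration, range, total distance and straightness. SE is `NA` for a
#'   single trip.
#' @export
summarize_trips <- function(tt) {
  if (is.null(tt) || nrow(tt) == 0L) stop("no trips to summarise")
  metrics <- c("duration_h", "foraging_range_km", "total_distance_km",
               "straightness")
  one <- function(sub, label) {
    row <- data.frame(destination = label, n = nrow(sub),
                      pct = 100 * nrow(sub) / nrow(tt))
    for (m in metrics) {
      v <- sub[[m]]
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_se")]] <- if (length(v) > 1)
        stats::sd(v) / sqrt(length(v)) else NA_real_
      row[[paste0(m, "_min")]] <- min(v)
      row[[paste0(m, "_max")]] <- max(v)
    }
    row
  }
  classes <- intersect(c("sea", "inland", "mixed", "island"),
                       unique(tt$destination))
  out <- do.call(rbind, c(
    lapply(classes, function(cl) one(tt[tt$destination == cl, ], cl)),
    list(one(tt, "overall"))))
  rownames(out) <- NULL
  out
}

#' Select trips for the land-sea ARS comparison
#'
#' Sea trips must reach at least the direct over-water distance to the
#' mainland coast (7.8 km, inclusive) so that marine and terrestrial trips
#' are compared over equal minimum ranges; mixed-destination and
#' island trips are excluded.
#'
#' @param tt Trip metrics table.
#' @param min_range_km Minimum foraging range for sea trips (km).
#' @return Filtered trip metrics table.
#' @export
filter_sea_trips <- function(tt, min_range_km = 7.8) {
  keep <- (tt$destination == "inland") |
    (tt$destination == "sea" & tt$foraging_range_km >= min_range_km)
  out <- tt[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
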