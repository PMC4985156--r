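# First-passage time (FPT): the time an animal takes to cross a circle of
# radius r centred on a point of its path. Moving the circle along the path
# gives a scale-dependent measure of search effort; peaks in var(log FPT)
# over r locate the spatial scale of area-restricted search (ARS).

#' Prepare a trip path for FPT analysis
#'
#' Resting bouts (maximal runs of fixes with device speed below
#' `rest_speed`, typically sitting on the water or on the ground) are
#' removed: each run collapses to a single point at the run's start
#' position, and the bout's duration is excised from subsequent timestamps,
#' so residence time in an ARS zone reflects active search rather than
#' drift or roosting. The remaining path is then resampled at a constant
#' along-path spacing with linearly interpolated timestamps.
#'
#' @param trip A `forage_trip` with at least two fixes.
#' @param rest_speed Resting/preening speed threshold (km/h).
#' @param spacing_km Along-path resampling interval (km).
#' @return An `fpt_path`: data frame with columns `lon`, `lat`, `x`, `y`
#'   (km on the local plane about the colony), `time_h` (hours since path
#'   start, rest bouts excised) and `timestamp`; spacing, colony and trip
#'   identity carried as attributes.
#' @export
preprocess_path <- function(trip, rest_speed = 3, spacing_km = 0.1) {
  f <- trip$fixes
  if (nrow(f) < 2L) stop("trip has fewer than 2 fixes")
  moving <- f$speed_kmh >= rest_speed
  if (!any(moving)) stop("all fixes below rest_speed: no path to analyse")

  t_h <- as.numeric(difftime(f$timestamp, f$timestamp[1], units = "hours"))
  r <- rle(!moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- rep(TRUE, nrow(f))
  shift <- rep(0, nrow(f))
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if (e > s) keep[(s + 1L):e] <- FALSE
    if (e < nrow(f)) shift[(e + 1L):nrow(f)] <-
        shift[(e + 1L):nrow(f)] + (t_h[e] - t_h[s])
  }
  t_adj <- t_h - shift
  lon <- f$lon[keep]; lat <- f$lat[keep]; tt <- t_adj[keep]

  cum <- path_cumdist_km(lon, lat)
  ok <- !duplicated(cum)
  lon <- lon[ok]; lat <- lat[ok]; tt <- tt[ok]; cum <- cum[ok]
  if (length(cum) < 2L || max(cum) < spacing_km)
    stop("path too short after rest-bout removal")

  targets <- seq(0, max(cum), by = spacing_km)
  out <- data.frame(
    lon = stats::approx(cum, lon, xout = targets)$y,
    lat = stats::approx(cum, lat, xout = targets)$y,
    time_h = stats::approx(cum, tt, xout = targets)$y)
  xy <- project_local(out$lon, out$lat, trip$colony)
  out$x <- xy[, 1]; out$y <- xy[, 2]
  out$timestamp <- f$timestamp[1] + out$time_h * 3600
  structure(out, class = c("fpt_path", "data.frame"),
            spacing_km = spacing_km, colony = trip$colony,
            individual = trip$individual, start = f$timestamp[1])
}

# FPT at evaluation points for a vector of radii. For each evaluation point
# the distance-from-centre series is scanned once; its running maximum is
# non-decreasing, so the first exit segment per radius is found by binary
# search, and the crossing time comes from linear interpolation of the
# distance-to-centre function along that segment (and symmetrically
# backwards for the last entry). Returns a length(idx) x length(radii)
# matrix; NA where the path starts or ends inside the circle.
fpt_matrix <- function(x, y, t, idx, radii) {
  n <- length(x)
  out <- matrix(NA_real_, length(idx), length(radii))
  for (q in seq_along(idx)) {
    i <- idx[q]
    # forward exit
    df <- sqrt((x[i:n] - x[i])^2 + (y[i:n] - y[i])^2)
    tf <- t[i:n]
    Mf <- cummax(df)
    kf <- findInterval(radii, Mf) + 1L
    okf <- kf <= length(Mf) & kf >= 2L
    # backward entry
    db <- sqrt((x[i:1] - x[i])^2 + (y[i:1] - y[i])^2)
    tb <- t[i:1]
    Mb <- cummax(db)
    kb <- findInterval(radii, Mb) + 1L
    okb <- kb <= length(Mb) & kb >= 2L
    ok <- okf & okb
    if (!any(ok)) next
    r <- radii[ok]; kf1 <- kf[ok]; kb1 <- kb[ok]
    ff <- (r - df[kf1 - 1L]) / (df[kf1] - df[kf1 - 1L])
    t_exit <- tf[kf1 - 1L] + ff * (tf[kf1] - tf[kf1 - 1L])
    fb <- (r - db[kb1 - 1L]) / (db[kb1] - db[kb1 - 1L])
    t_entry <- tb[kb1 - 1L] + fb * (tb[kb1] - tb[kb1 - 1L])
    out[q, ok] <- t_exit - t_entry
  }
  out
}

#' First-passage time along a path for one radius
#'
#' FPT at a point is the time between the last entry into and the first
#' exit from the circle of radius `radius` centred there, found by walking
#' the path backwards and forwards with circle crossings located by linear
#' interpolation of the distance-to-centre function along segments.
#' Undefined (NA) where the path starts or ends inside the circle.
#'
#' @param path An `fpt_path` from [preprocess_path()].
#' @param radius Circle radius (km), > 0.
#' @return Numeric vector of FPT values (hours), one per path point.
#' @export
compute_fpt <- function(path, radius) {
  if (length(radius) != 1L || radius <= 0) stop("radius must be a single value > 0")
  drop(fpt_matrix(path$x, path$y, path$time_h, seq_len(nrow(path)), radius))
}

#' Variance-of-log(FPT) spectrum over a radius grid
#'
#' Computes FPT at evaluation points spaced `eval_spacing_km` along the
#' path for every radius in `r_grid`, log-transforms (natural log, making
#' the variance independent of the FPT magnitude), and takes the variance
#' per radius over defined values. Local maxima of the variance curve are
#' candidate ARS scales, largest variance first. The canonical two-step
#' analysis uses `r_grid = 1:50` evaluated every 1 km for large scales and
#' `r_grid = seq(0.1, 10, 0.1)` evaluated every 0.1 km for nested small
#' scales.
#'
#' @param path An `fpt_path`.
#' @param r_grid Increasing positive radii (km).
#' @param eval_spacing_km Spacing of evaluation points along the path (km);
#'   defaults to the path's own spacing.
#' @return An `fpt_profile`: list with `radii`, `eval_idx`, `fpt` (matrix,
#'   evaluation points x radii), `var_log` (NA where fewer than 3 FPT
#'   values are defined) and `peaks` (data frame `radius`, `var_log`,
#'   ordered by decreasing variance).
#' @export
variance_spectrum <- function(path, r_grid = seq(0.1, 10, by = 0.1),
                              eval_spacing_km = attr(path, "spacing_km")) {
  if (any(r_grid <= 0) || is.unsorted(r_grid, strictly = TRUE))
    stop("r_grid must be positive and strictly increasing")
  spacing <- attr(path, "spacing_km")
  stride <- max(1L, as.integer(round(eval_spacing_km / spacing)))
  idx <- seq(1L, nrow(path), by = stride)
  fpt <- fpt_matrix(path$x, path$y, path$time_h, idx, r_grid)
  var_log <- apply(fpt, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 3L) return(NA_real_)
    stats::var(log(v))
  })
  peaks <- local_maxima(r_grid, var_log)
  structure(list(radii = r_grid, eval_idx = idx, fpt = fpt,
                 var_log = var_log, peaks = peaks,
                 spacing_km = spacing, individual = attr(path, "individual")),
            class = "fpt_profile")
}

local_maxima <- function(r, v) {
  n <- length(v)
  is_peak <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    left <- if (i > 1L) v[i - 1L] else -Inf
    right <- if (i < n) v[i + 1L] else -Inf
    left <- if (is.na(left)) -Inf else left
    right <- if (is.na(right)) -Inf else right
    if (v[i] > left && v[i] >= right) is_peak[i] <- TRUE
  }
  out <- data.frame(radius = r[is_peak], var_log = v[is_peak])
  out[order(-out$var_log), , drop = FALSE]
}

#' @export
print.fpt_profile <- function(x, ...) {
  cat(sprintf("FPT profile: %d radii in [%g, %g] km, %d evaluation points\n",
              length(x$radii), min(x$radii), max(x$radii),
              length(x$eval_idx)))
  if (nrow(x$peaks)) {
    cat("  variance peaks (largest first):\n")
    top <- utils::head(x$peaks, 3)
    for (j in seq_len(nrow(top)))
      cat(sprintf("    r = %g km, var(log FPT) = %.3f\n",
                  top$radius[j], top$var_log[j]))
  } else cat("  no variance peaks\n")
  invisible(x)
}

#' @export
plot.fpt_profile <- function(x, ...) {
  graphics::plot(x$radii, x$var_log, type = "l",
                 xlab = "radius r (km)", ylab = "var(log FPT)", ...)
  if (nrow(x$peaks))
    graphics::points(x$peaks$radius, x$peaks$var_log, pch = 19)
  invisible(x)
}

# Otsu's criterion on log(FPT): threshold maximising the between-class
# variance of a two-group split. Returns the threshold on the natural scale
# and the separability (between/total variance ratio) of the best split.
otsu_split <- function(v) {
  x <- sort(log(v))
  n <- length(x)
  if (n < 4L || stats::var(x) == 0)
    return(list(threshold = exp(stats::median(x)), separability = 0))
  csum <- cumsum(x)
  total_mu <- csum[n] / n
  k <- seq_len(n - 1L)
  w1 <- k / n
  mu1 <- csum[k] / k
  mu2 <- (csum[n] - csum[k]) / (n - k)
  sb <- w1 * (1 - w1) * (mu1 - mu2)^2
  best <- which.max(sb)
  list(threshold = exp((x[best] + x[best + 1L]) / 2),
       separability = sb[best] / (stats::var(x) * (n - 1) / n))
}

#' Automatic FPT threshold for ARS delineation
#'
#' Replaces the by-eye inspection of the FPT frequency distribution with a
#' reproducible rule: an Otsu two-class split of log(FPT). When the split
#' is weak (between-class separability below `min_separability`, i.e. the
#' distribution looks unimodal) the 75th percentile is used instead.
#'
#' @param fpt Numeric FPT values (NA allowed).
#' @param min_separability Otsu separability below which the quantile
#'   fallback applies.
#' @return Threshold (hours), with attributes `method` and `separability`.
#' @export
fpt_threshold <- function(fpt, min_separability = 0.5) {
  v <- fpt[!is.na(fpt) & fpt > 0]
  if (!length(v)) stop("no defined FPT values")
  sp <- otsu_split(v)
  if (sp$separability >= min_separability) {
    structure(sp$threshold, method = "otsu", separability = sp$separability)
  } else {
    structure(unname(stats::quantile(v, 0.75)), method = "quantile75",
              separability = sp$separability)
  }
}

#' Delineate ARS zones at a detected scale
#'
#' Thresholds the FPT series at radius `r_star` (the radius of maximum
#' var(log FPT)); maximal contiguous above-threshold runs become zones.
#' Each zone reports its entry time (first above-threshold timestamp), the
#' maximum FPT (maximum residence time), the position of that maximum, and
#' its great-circle distance to the colony.
#'
#' @param path An `fpt_path`.
#' @param r_star Scale radius (km), typically a [variance_spectrum()] peak.
#' @param colony Colony (lon, lat); defaults to the path's own.
#' @param threshold FPT threshold in hours; computed by [fpt_threshold()]
#'   when `NULL`.
#' @return Data frame of zones (possibly 0 rows): `zone`, `r_star_km`,
#'   `entry_time`, `max_fpt_h`, `lon`, `lat`, `distance_to_colony_km`,
#'   `n_points`; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
detect_ars_zones <- function(path, r_star, colony = NULL, threshold = NULL) {
  if (is.null(colony)) colony <- attr(path, "colony")
  fpt <- compute_fpt(path, r_star)
  if (is.null(threshold)) threshold <- fpt_threshold(fpt)
  above <- !is.na(fpt) & fpt > as.numeric(threshold)
  empty <- data.frame(zone = integer(), r_star_km = numeric(),
                      entry_time = as.POSIXct(character(), tz = "UTC"),
                      max_fpt_h = numeric(), lon = numeric(), lat = numeric(),
                      distance_to_colony_km = numeric(),
                      n_points = integer())
  if (!any(above)) {
    attr(empty, "threshold") <- threshold
    return(empty)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    imax <- s + which.max(fpt[s:e]) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      zone = length(rows) + 1L, r_star_km = r_star,
      entry_time = path$timestamp[s], max_fpt_h = fpt[imax],
      lon = path$lon[imax], lat = path$lat[imax],
      distance_to_colony_km = gc_dist_km(colony[1], colony[2],
                                         path$lon[imax], path$lat[imax]),
      n_points = e - s + 1L)
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Full two-step ARS analysis of one trip
#'
#' Runs [preprocess_path()], computes the large-scale (1-50 km, every
#' 1 km) and nested small-scale (0.1-10 km, every 0.1 km) variance
#' spectra, pools their variance peaks, keeps up to `max_scales` distinct
#' peak radii (highest variance first), and delineates ARS zones at each.
#' Scales are labelled 1st, 2nd, 3rd by *descending* radius, so the 1st
#' scale is the coarsest.
#'
#' @param trip A `forage_trip`.
#' @param rest_speed,spacing_km Passed to [preprocess_path()].
#' @param r_grid_large,r_grid_small Radius grids (km).
#' @param eval_large_km,eval_small_km Evaluation spacings (km).
#' @param max_scales Maximum number of ARS scales per trip.
#' @return List of class `ars_analysis`: `path`, `profile_large`,
#'   `profile_small`, `scales` (data frame `scale`, `radius`), and
#'   `zones` (data frame with a `scale` column; 0 rows when no ARS).
#' @export
ars_analysis <- function(trip, rest_speed = 3, spacing_km = 0.1,
                         r_grid_large = seq(1, 50, by = 1),
                         r_grid_small = seq(0.1, 10, by = 0.1),
                         eval_large_km = 1, eval_small_km = 0.1,
                         max_scales = 3L) {
  path <- preprocess_path(trip, rest_speed, spacing_km)
  prof_l <- variance_spectrum(path, r_grid_large, eval_large_km)
  prof_s <- variance_spectrum(path, r_grid_small, eval_small_km)
  peaks <- rbind(prof_l$peaks, prof_s$peaks)
  peaks <- peaks[!duplicated(peaks$radius), , drop = FALSE]
  peaks <- utils::head(peaks[order(-peaks$var_log), , drop = FALSE],
                       max_scales)
  zones <- list()
  scales <- NULL
  if (nrow(peaks)) {
    radii <- sort(peaks$radius, decreasing = TRUE)
    scales <- data.frame(scale = paste0(c("1st", "2nd", "3rd")[seq_along(radii)]),
                         radius = radii)
    for (j in seq_along(radii)) {
      z <- detect_ars_zones(path, radii[j])
      if (nrow(z)) {
        z$scale <- scales$scale[j]
        zones[[length(zones) + 1L]] <- z
      }
    }
  }
  zones <- if (length(zones)) do.call(rbind, zones) else NULL
  structure(list(path = path, profile_large = prof_l, profile_small = prof_s,
                 scales = scales, zones = zones,
                 individual = trip$individual),
            class = "ars_analysis")
}

#' @export
print.ars_analysis <- function(x, ...) {
  cat("ARS analysis:", x$individual, "\n")
  if (is.null(x$scales)) {
    cat("  no ARS scales detected\n")
  } else {
    for (j in seq_len(nrow(x$scales)))
      cat(sprintf("  %s scale: r* = %g km\n", x$scales$scale[j],
                  x$scales$radius[j]))
    nz <- if (is.null(x$zones)) 0L else nrow(x$zones)
    cat("  zones:", nz, "\n")
  }
  invisible(x)
}

#' Summarise ARS zones across trips
#'
#' @param zones Data frame of zones pooled over trips (needs columns
#'   `scale`, `r_star_km`, `max_fpt_h`, `distance_to_colony_km`; extra
#'   grouping columns such as `destination` are honoured via `by`).
#' @param by Optional name of a grouping column (e.g. `"destination"`).
#' @return Data frame of zone counts and mean +/- SE of radius, maximum
#'   FPT (h) and distance to colony, per scale (plus all scales pooled,
#'   the colony-level block) and per group.
#' @export
summarize_ars <- function(zones, by = NULL) {
  if (is.null(zones) || nrow(zones) == 0L) stop("no ARS zones to summarise")
  groups <- if (is.null(by)) list(all = zones) else split(zones, zones[[by]])
  mse <- function(v) c(mean = mean(v),
                       se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                            else NA_real_)
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    blocks <- c(list(colony_level = sub), split(sub, sub$scale))
    for (b in names(blocks)) {
      z <- blocks[[b]]
      if (!nrow(z)) next
      r <- mse(z$r_star_km); f <- mse(z$max_fpt_h)
      d <- mse(z$distance_to_colony_km)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, scale = b, n_zones = nrow(z),
        radius_mean = r["mean"], radius_se = r["se"],
        max_fpt_h_mean = f["mean"], max_fpt_h_se = f["se"],
        distance_km_mean = d["mean"], distance_km_se = d["se"],
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Export ARS zones as GeoJSON points
#'
#' @param zones Zone data frame (as from [ars_analysis()], pooled).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(seq_len(nrow(zones)), function(i) {
    props <- as.list(zones[i, setdiff(names(zones), c("lon", "lat")),
                           drop = FALSE])
    props <- lapply(props, function(v)
      if (inherits(v, "POSIXct")) format(v, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      else v)
    list(type = "Feature", properties = props,
         geometry = list(type = "Point",
                         coordinates = c(zones$lon[i], zones$lat[i])))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}
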