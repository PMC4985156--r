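# Shared fixtures: a minimal coastal mask, constructors for hand-built trips
# and paths on the local plane, and an independent brute-force FPT oracle.

TEST_COLONY <- c(7.76, 53.78)

# Stylised geography: elongated island at the colony, tidal-flat strip,
# mainland south of a coast 7.8 km from the colony, open sea elsewhere.
make_test_mask <- function(colony = TEST_COLONY) {
  ring_xy <- function(x, y) {
    ll <- dualforage:::unproject_local(x, y, colony)
    cbind(ll[, "lon"], ll[, "lat"])
  }
  theta <- seq(0, 2 * pi, length.out = 73)
  rect <- function(x1, x2, y1, y2)
    ring_xy(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1))
  landscape_mask(
    list(island = ring_xy(5 * cos(theta), 1.5 * sin(theta)),
         tidal_flat = rect(-25, 25, -7.8, -1.8),
         mainland = rect(-150, 150, -120, -7.8)),
    colony, default_class = "sea", colony_buffer_km = 0.5)
}

# Fix series from projected-km waypoints: timestamps every `dt_min`,
# device speed = step length / dt unless given explicitly.
make_series <- function(x, y, dt_min = 3, speed = NULL, id = "t01",
                        colony = TEST_COLONY,
                        t0 = as.POSIXct("2010-05-20 08:00:00", tz = "UTC")) {
  ll <- dualforage:::unproject_local(x, y, colony)
  n <- length(x)
  if (is.null(speed)) {
    step <- sqrt(diff(x)^2 + diff(y)^2)
    speed <- c(step[1], step) / (dt_min / 60)
  }
  data.frame(id = id, timestamp = t0 + (seq_len(n) - 1) * dt_min * 60,
             lon = ll[, "lon"], lat = ll[, "lat"], speed_kmh = speed)
}

# A forage_trip directly from projected waypoints (complete by construction).
make_trip <- function(x, y, dt_min = 3, speed = NULL, id = "t01",
                      colony = TEST_COLONY, complete = TRUE) {
  f <- make_series(x, y, dt_min, speed, id, colony)
  structure(list(individual = id, fixes = f, start = f$timestamp[1],
                 end = f$timestamp[nrow(f)], complete = complete,
                 colony = colony),
            class = "forage_trip")
}

# Deterministic path fixture: fast straight commute with slow dense zigzag
# "patches" at the given along-track centre distances (km along +y).
make_patch_series <- function(patch_centers_km, patch_halfwidth_km = 1,
                              commute_speed = 40, patch_speed = 5,
                              dt_min = 3, end_km = NULL) {
  dt_h <- dt_min / 60
  if (is.null(end_km)) end_km <- max(patch_centers_km) + 10
  xs <- 0; ys <- 0
  pos <- 0
  for (ctr in sort(patch_centers_km)) {
    while (pos + commute_speed * dt_h < ctr) {
      pos <- pos + commute_speed * dt_h
      xs <- c(xs, 0); ys <- c(ys, pos)
    }
    # zigzag across the patch at low speed
    step <- patch_speed * dt_h
    xoff <- 0; sgn <- 1
    for (k in 1:80) {
      xoff <- xoff + sgn * step
      if (abs(xoff) >= patch_halfwidth_km) sgn <- -sgn
      xs <- c(xs, xoff); ys <- c(ys, ctr)
    }
    pos <- ctr
  }
  while (pos < end_km) {
    pos <- pos + commute_speed * dt_h
    xs <- c(xs, 0); ys <- c(ys, pos)
  }
  # return leg
  while (pos > commute_speed * dt_h) {
    pos <- pos - commute_speed * dt_h
    xs <- c(xs, 0); ys <- c(ys, pos)
  }
  xs <- c(xs, 0); ys <- c(ys, 0)
  make_trip(xs, ys)
}

# One-way straight path at constant speed, resampled for FPT analysis.
straight_path <- function(length_km = 60, speed = 30, spacing = 0.1) {
  n_fix <- ceiling(length_km / (speed * 0.05)) + 1
  y <- (seq_len(n_fix) - 1) * speed * 0.05
  tr <- make_trip(rep(0, n_fix), y, dt_min = 3)
  preprocess_path(tr, rest_speed = 3, spacing_km = spacing)
}

# Independent brute-force FPT: for each evaluation point walk every segment
# outward in both directions, find the first distance exceeding r, and
# interpolate the crossing time linearly in the distance-to-centre function.
oracle_fpt <- function(path, radius) {
  x <- path$x; y <- path$y; t <- path$time_h
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    df <- sqrt((x[i:n] - x[i])^2 + (y[i:n] - y[i])^2)
    jf <- which(df > radius)[1]
    if (is.na(jf)) next
    tf <- t[i:n]
    ff <- (radius - df[jf - 1]) / (df[jf] - df[jf - 1])
    t_exit <- tf[jf - 1] + ff * (tf[jf] - tf[jf - 1])
    db <- sqrt((x[i:1] - x[i])^2 + (y[i:1] - y[i])^2)
    jb <- which(db > radius)[1]
    if (is.na(jb)) next
    tb <- t[i:1]
    fb <- (radius - db[jb - 1]) / (db[jb] - db[jb - 1])
    t_entry <- tb[jb - 1] + fb * (tb[jb] - tb[jb - 1])
    out[i] <- t_exit - t_entry
  }
  out
}

# Random-walk path fixture for oracle-equivalence checks: n points on the
# local plane, irregular step lengths and times, wrapped into an fpt_path.
random_walk_path <- function(n = 200, seed = 1) {
  set.seed(seed)
  step <- stats::runif(n - 1, 0.05, 0.6)
  theta <- cumsum(stats::rnorm(n - 1, 0, 0.6))
  x <- c(0, cumsum(step * sin(theta)))
  y <- c(0, cumsum(step * cos(theta)))
  t_h <- c(0, cumsum(stats::runif(n - 1, 0.01, 0.1)))
  ll <- dualforage:::unproject_local(x, y, TEST_COLONY)
  structure(data.frame(lon = ll[, "lon"], lat = ll[, "lat"],
                       x = x, y = y, time_h = t_h,
                       timestamp = as.POSIXct("2010-05-20", tz = "UTC") +
                         t_h * 3600),
            class = c("fpt_path", "data.frame"), spacing_km = 0.1,
            colony = TEST_COLONY, individual = "rw",
            start = as.POSIXct("2010-05-20", tz = "UTC"))
}

# Availability-versus-use table from plain counts (no survey needed).
table_from_counts <- function(avail, use) {
  survey <- data.frame(segment_id = seq_len(sum(avail)),
                       habitat = rep(names(avail), avail))
  spots <- data.frame(habitat = rep(names(use), use), primary = TRUE)
  habitat_table(survey, spots)
}

# Coastal-farmland availability counts and feeding-spot counts used for the
# worked habitat-selection examples (1292 survey segments, 38 spots).
farmland_availability <- function() {
  c(grassland = 824, corn = 248, winter_wheat = 90, barley = 61, rye = 15,
    potato = 12, rape = 10, oat = 8, fallow_land = 6, construction_area = 6,
    ploughed_soil = 5, summer_wheat = 3, water_body = 2, pea = 2,
    waste_disposal = 0)
}

farmland_use <- function() {
  c(grassland = 17, corn = 12, winter_wheat = 0, barley = 0, rye = 0,
    potato = 6, rape = 0, oat = 0, fallow_land = 0, construction_area = 1,
    ploughed_soil = 1, summer_wheat = 0, water_body = 0, pea = 0,
    waste_disposal = 1)
}
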