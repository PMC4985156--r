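# Trip ingestion, segmentation, metrics, destination classes and budgets.

test_that("read_fixes parses, sorts, deduplicates and speed-filters", {
  f <- tempfile(fileext = ".csv")
  base <- as.POSIXct("2010-05-20 10:00:00", tz = "UTC")
  mk <- function(ts, lon, lat, spd, id = "b1")
    sprintf("%s,%s,%.6f,%.6f,%.1f", id,
            format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), lon, lat, spd)
  # three well-formed rows, out of order
  writeLines(c("id,timestamp_utc,lon,lat,speed_kmh",
               mk(base + 360, 7.77, 53.78, 30),
               mk(base, 7.76, 53.78, 30),
               mk(base + 180, 7.765, 53.78, 30)), f)
  out <- read_fixes(f)
  expect_length(out, 1)
  expect_equal(nrow(out$b1), 3)
  expect_true(!is.unsorted(out$b1$timestamp, strictly = TRUE))

  # duplicated timestamp collapses to the first occurrence
  writeLines(c("id,timestamp_utc,lon,lat,speed_kmh",
               mk(base, 7.76, 53.78, 30),
               mk(base, 7.99, 53.78, 30),
               mk(base + 180, 7.765, 53.78, 30)), f)
  out <- read_fixes(f)
  expect_equal(nrow(out$b1), 2)
  expect_equal(attr(out, "report")$n_duplicates, 1)
  expect_equal(out$b1$lon[1], 7.76)

  # a fix 100 km from its 3-min-earlier neighbour implies 2000 km/h > 150
  far <- dualforage:::unproject_local(0, 100, c(7.76, 53.78))
  expect_equal(gc_dist_km(7.76, 53.78, far[1], far[2]), 100, tolerance = 1e-6)
  writeLines(c("id,timestamp_utc,lon,lat,speed_kmh",
               mk(base, 7.76, 53.78, 30),
               mk(base + 180, far[1], far[2], 30),
               mk(base + 360, 7.765, 53.781, 30)), f)
  out <- suppressMessages(read_fixes(f, max_speed = 150))
  expect_equal(nrow(out$b1), 2)
  expect_equal(attr(out, "report")$n_speed_dropped, 1)
})

test_that("read_fixes skips malformed rows and errors on empty files", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,timestamp_utc,lon,lat,speed_kmh",
               "b1,2010-05-20T10:00:00Z,7.76,53.78,30",
               "b1,not-a-time,7.76,53.78,30",
               "b1,2010-05-20T10:03:00Z,oops,53.78,30"), f)
  out <- suppressMessages(read_fixes(f))
  expect_equal(nrow(out$b1), 1)
  writeLines("id,timestamp_utc,lon,lat,speed_kmh", f)
  expect_error(read_fixes(f), "empty")
})

test_that("segmentation finds colony-bounded excursions and skips dwell", {
  mask <- make_test_mask()
  # all fixes within 0.4 km of the colony: no trips
  s <- make_series(c(0, 0.1, 0.2, 0.1), c(0, 0.2, 0.1, 0), speed = rep(1, 4))
  expect_length(segment_trips(s, mask, buffer_km = 0.5), 0)

  # 2-h out-and-back crossing the buffer once each way
  y <- c(0.1, seq(2, 20, by = 2), seq(20, 2, by = -2), 0.1)
  s <- make_series(rep(0, length(y)), y, dt_min = 3)
  trips <- segment_trips(s, mask, buffer_km = 0.5, min_duration_h = 0.25)
  expect_length(trips, 1)
  tr <- trips[[1]]
  expect_true(tr$complete)
  # extended to the bounding buffer-crossing fixes (the 0.1-km dwell fixes)
  expect_equal(tr$fixes$timestamp[1], s$timestamp[1])
  expect_equal(tr$fixes$timestamp[nrow(tr$fixes)], s$timestamp[nrow(s)])

  # two excursions separated by colony dwell give two trips
  y2 <- c(0.1, 5, 10, 5, rep(0.1, 20), 5, 10, 5, 0.1)
  s2 <- make_series(rep(0, length(y2)), y2, dt_min = 3)
  expect_length(segment_trips(s2, mask, min_duration_h = 0.1), 2)
})

test_that("trip metrics match hand-evaluated range, distance and straightness", {
  mask <- make_test_mask()
  # straight out-and-back to 30 km
  y <- c(0, seq(1, 30), seq(29, 0))
  tr <- make_trip(rep(0, length(y)), y)
  m <- trip_metrics(tr, mask)
  expect_equal(m$foraging_range_km, 30, tolerance = 1e-6)
  expect_equal(m$total_distance_km, 60, tolerance = 1e-6)
  expect_equal(m$straightness, 1.0)

  # loop with range 30 km and total path 100 km: straightness 0.600
  y <- c(0, seq(1, 30), c(20, 30, 20, 30), seq(29, 0))
  tr <- make_trip(rep(0, length(y)), y)
  m <- trip_metrics(tr, mask)
  expect_equal(m$foraging_range_km, 30, tolerance = 1e-6)
  expect_equal(m$total_distance_km, 100, tolerance = 1e-6)
  expect_equal(m$straightness, 0.600, tolerance = 1e-6)

  # degenerate single-fix trip errors
  tr1 <- make_trip(0, 10)
  expect_error(trip_metrics(tr1, mask), "degenerate")
})

test_that("total distance is invariant to collinear intermediate fixes", {
  mask <- make_test_mask()
  y <- c(0, 10, 20, 30, 20, 10, 0)
  tr_coarse <- make_trip(rep(0, 7), y, dt_min = 15)
  y_fine <- c(seq(0, 30, by = 2.5), seq(27.5, 0, by = -2.5))
  tr_fine <- make_trip(rep(0, length(y_fine)), y_fine, dt_min = 5)
  m1 <- trip_metrics(tr_coarse, mask)
  m2 <- trip_metrics(tr_fine, mask)
  expect_equal(m1$total_distance_km, m2$total_distance_km,
               tolerance = 1e-6)
})

test_that("destination classes follow the dwell-fix rule", {
  mask <- make_test_mask()
  mk_dwell <- function(ys, dwell_x = 0) {
    # commute out fast, dwell slow at the listed projected offsets
    x <- c(0, rep(dwell_x, length(ys)), 0)
    y <- c(0, ys, 0)
    spd <- c(40, rep(2, length(ys)), 40)
    make_trip(x, y, speed = spd)
  }
  expect_identical(classify_destination(mk_dwell(rep(15, 6)), mask), "sea")
  expect_identical(classify_destination(mk_dwell(rep(-15, 6)), mask), "inland")
  expect_identical(classify_destination(mk_dwell(c(15, 15, 15, -15, -15, -15)),
                                        mask), "mixed")
  # dwell only on the island
  tr <- make_trip(c(0, 3, 3, 3, 0), c(0, 0.5, 0.6, 0.5, 0),
                  speed = c(40, 2, 2, 2, 40))
  expect_identical(classify_destination(tr, mask), "island")
  # no dwell fixes: most distant fix decides
  tr <- make_trip(c(0, 0, 0, 0), c(0, 10, 20, 0), speed = rep(40, 4))
  expect_identical(classify_destination(tr, mask), "sea")
})

test_that("summary reproduces class percentages and SE conventions", {
  tt <- data.frame(
    destination = rep(c("sea", "inland", "mixed", "island"), c(52, 47, 7, 2)),
    duration_h = 8, foraging_range_km = 30, total_distance_km = 100,
    straightness = 0.7)
  s <- summarize_trips(tt)
  expect_equal(s$n[match(c("sea", "inland", "mixed", "island"),
                         s$destination)], c(52, 47, 7, 2))
  expect_equal(round(s$pct[match(c("sea", "inland", "mixed", "island"),
                                 s$destination)], 1),
               c(48.1, 43.5, 6.5, 1.9))
  expect_equal(sum(s$n[s$destination != "overall"]), 108)
  # identical trips: SE 0; single trip: SE reported as NA
  expect_equal(s$duration_h_se[s$destination == "sea"], 0)
  one <- summarize_trips(tt[1, ])
  expect_true(is.na(one$duration_h_se[1]))
  expect_error(summarize_trips(tt[0, ]), "no trips")
})

test_that("diel budget separates daylight land use from night sea use", {
  mask <- make_test_mask()
  t0 <- as.POSIXct("2010-05-20 00:00:00", tz = "UTC")  # local = UTC + 2
  mk_fix_trip <- function(times, x, y, id) {
    ll <- dualforage:::unproject_local(x, y, TEST_COLONY)
    f <- data.frame(id = id, timestamp = times, lon = ll[, "lon"],
                    lat = ll[, "lat"], speed_kmh = 5)
    structure(list(individual = id, fixes = f, start = times[1],
                   end = times[length(times)], complete = TRUE,
                   colony = TEST_COLONY), class = "forage_trip")
  }
  # land fixes 12:00-18:00 local (10:00-16:00 UTC)
  land_times <- t0 + seq(10 * 3600, 16 * 3600, by = 1800)
  n1 <- length(land_times)
  land_trip <- mk_fix_trip(land_times, rep(0, n1), rep(-15, n1), "b1")
  # sea fixes 00:00-04:00 local
  sea_times <- t0 + seq(-2 * 3600, 2 * 3600, by = 1800)
  n2 <- length(sea_times)
  sea_trip <- mk_fix_trip(sea_times, rep(0, n2), rep(15, n2), "b1")
  b <- diel_budget(list(land_trip, sea_trip), mask, utc_offset = 2)
  expect_equal(b$land_share_mean[b$hour == 13], 1.0)
  expect_equal(b$land_share_mean[b$hour == 2], 0.0)
  expect_equal(b$n_individuals[b$hour == 8], 0)       # empty bin flagged
  expect_true(is.na(b$land_share_mean[b$hour == 8]))
  # all-sea data: sea share 1 in every non-empty bin
  b2 <- diel_budget(list(sea_trip), mask, utc_offset = 2)
  expect_true(all(b2$sea_share_mean[b2$n_individuals > 0] == 1))
})

test_that("variance-ratio F test is symmetric and matches known ratios", {
  a <- c(1, 2, 3, 4, 5)
  r1 <- variance_ratio_test(a, a)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$p_value, 1)
  set.seed(1)
  x <- rnorm(2000); y <- rnorm(2000)
  a <- as.numeric(scale(x)) * 2   # sample variance exactly 4
  b <- as.numeric(scale(y))       # sample variance exactly 1
  r <- variance_ratio_test(a, b)
  expect_equal(r$statistic, 4, tolerance = 1e-12)
  rs <- variance_ratio_test(b, a)
  expect_equal(rs$statistic, 1 / r$statistic, tolerance = 1e-12)
  expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
  expect_error(variance_ratio_test(a, rep(1, 5)), "zero variance")
})

test_that("destination classes partition the trips of a simulated colony", {
  cfg <- sim_config(seed = 23, n_individuals = 2, n_trips_per_individual = 4)
  fx <- simulate_tracks(cfg)
  mask <- simulate_landscape(cfg)$mask
  trips <- unlist(lapply(split(fx, fx$id), segment_trips, mask = mask),
                  recursive = FALSE)
  tt <- trips_table(trips, mask)
  s <- summarize_trips(tt)
  expect_equal(sum(s$n[s$destination != "overall"]), nrow(tt))
  expect_true(all(tt$foraging_range_km <= tt$total_distance_km))
  expect_true(all(tt$straightness > 0 & tt$straightness <= 1))
})
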