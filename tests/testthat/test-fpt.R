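# First-passage time: closed form, oracle equivalence, spectra, zones.

test_that("FPT on a straight constant-speed path matches 2r/v", {
  path <- straight_path(60, 30, 0.1)
  for (r in c(0.5, 1, 5)) {
    fpt <- compute_fpt(path, r)
    d_end <- pmin(path$time_h * 30, max(path$time_h * 30) - path$time_h * 30)
    interior <- which(d_end > r + 0.2)
    expect_true(all(!is.na(fpt[interior])))
    expect_true(all(abs(fpt[interior] - 2 * r / 30) < 0.1 / 30))
  }
})

test_that("a radius exceeding the path extent leaves FPT undefined everywhere", {
  path <- straight_path(10, 30)
  expect_true(all(is.na(compute_fpt(path, 50))))
  expect_error(compute_fpt(path, -1), "radius")
  expect_error(compute_fpt(path, c(1, 2)), "single")
})

test_that("FPT equals the brute-force crossing-time oracle exactly", {
  for (seed in 1:5) {
    path <- random_walk_path(n = 200, seed = seed)
    for (r in c(0.3, 1, 3)) {
      expect_identical(compute_fpt(path, r), oracle_fpt(path, r))
    }
  }
})

test_that("FPT is monotone non-decreasing in the radius", {
  path <- random_walk_path(n = 150, seed = 42)
  radii <- c(0.2, 0.5, 1, 2, 4)
  m <- dualforage:::fpt_matrix(path$x, path$y, path$time_h,
                               seq_len(nrow(path)), radii)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    v <- v[!is.na(v)]
    if (length(v) > 1) expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("rest bouts are excised: path length unchanged, residence reduced", {
  y_out <- seq(0, 30, by = 2); y_back <- seq(28, 0, by = -2)
  y <- c(y_out, y_back)
  tr_nobout <- make_trip(rep(0, length(y)), y)

  # same geometry with a 2-h rest bout (41 fixes at 3 min) inserted at 30 km
  n_rest <- 41
  y_b <- c(y_out, rep(30, n_rest), y_back)
  spd <- c(rep(40, length(y_out)), rep(0.5, n_rest), rep(40, length(y_back) + 1))
  tr_bout <- make_trip(rep(0, length(y_b)), y_b, speed = spd[seq_along(y_b)])

  p0 <- preprocess_path(tr_nobout)
  p1 <- preprocess_path(tr_bout)
  expect_equal(nrow(p1), nrow(p0))
  # excision leaves at most one residual fix interval (0.05 h) of bout time
  expect_equal(max(p1$time_h), max(p0$time_h), tolerance = 0.051)

  # leaving the bout in (rest threshold below the bout speed) inflates FPT
  p2 <- preprocess_path(tr_bout, rest_speed = 0.1)
  f1 <- compute_fpt(p1, 2); f2 <- compute_fpt(p2, 2)
  i30 <- which.min(abs(p1$y - 30))
  expect_lt(f1[i30], f2[which.min(abs(p2$y - 30))] - 1.5)
  f0 <- compute_fpt(p0, 2)[which.min(abs(p0$y - 30))]
  expect_lt(abs(f1[i30] - f0), 0.06)   # within one residual fix interval
  # a trip resting throughout cannot be analysed
  tr_all_rest <- make_trip(c(0, 0.1, 0.2), c(0, 0.1, 0.2), speed = rep(1, 3))
  expect_error(preprocess_path(tr_all_rest), "rest_speed")
})

test_that("resampling arithmetic: 10 km at 0.1 km spacing gives 101 points", {
  path <- straight_path(10, 20, 0.1)
  expect_equal(nrow(path), 101)
  expect_true(all(abs(diff(path$y) - 0.1) < 1e-6))
})

test_that("variance spectrum is flat on a straight path and peaks at a patch", {
  path <- straight_path(40, 30, 0.1)
  prof <- variance_spectrum(path, r_grid = seq(1, 10), eval_spacing_km = 1)
  v <- prof$var_log[!is.na(prof$var_log)]
  expect_true(all(v < 1e-6))

  tr <- make_patch_series(30, patch_halfwidth_km = 2.5)
  prof <- variance_spectrum(preprocess_path(tr), r_grid = seq(1, 20),
                            eval_spacing_km = 1)
  expect_gt(nrow(prof$peaks), 0)
  top <- prof$peaks$radius[1]
  expect_gte(top, 2.5 / 2 * 2)  # patch diameter 5 km: peak in [2.5, 10]
  expect_lte(top, 10)
})

test_that("two-step default grids cover 1-50 km and 0.1-10 km", {
  fm <- formals(ars_analysis)
  expect_equal(eval(fm$r_grid_large), seq(1, 50, by = 1))
  expect_equal(eval(fm$r_grid_small), seq(0.1, 10, by = 0.1))
  expect_error(variance_spectrum(straight_path(10), r_grid = c(2, 1)),
               "increasing")
})

test_that("thresholded FPT runs become zones with residence metrics", {
  tr <- make_patch_series(c(20, 40), patch_halfwidth_km = 1, end_km = 50)
  path <- preprocess_path(tr)
  fpt <- compute_fpt(path, 1.5)
  thr <- 2 * 1.5 / 40 * 3   # well above commuting FPT, below patch residence
  z <- detect_ars_zones(path, 1.5, threshold = thr)
  expect_equal(nrow(z), 2)
  expect_true(all(z$max_fpt_h > thr))
  expect_equal(sort(z$distance_to_colony_km), c(20, 40), tolerance = 1)
  # zones are time-disjoint and within the trip span
  expect_lt(z$entry_time[1], z$entry_time[2])
  expect_true(all(z$entry_time >= path$timestamp[1] &
                    z$entry_time <= path$timestamp[nrow(path)]))
  # max_fpt equals the block maximum
  above <- !is.na(fpt) & fpt > thr
  expect_equal(max(z$max_fpt_h), max(fpt[above]))
  # one contiguous block gives one zone
  z1 <- detect_ars_zones(preprocess_path(make_patch_series(20, end_km = 30)),
                         1.5, threshold = thr)
  expect_equal(nrow(z1), 1)
  # no above-threshold run gives an empty collection
  z0 <- detect_ars_zones(straight_path(30), 1, threshold = 10)
  expect_equal(nrow(z0), 0)
})

test_that("a simulated patch 40 km out is recovered at the right distance", {
  cfg <- sim_config(seed = 31, n_individuals = 1, n_trips_per_individual = 1,
                    p_sea = 1, sea_range_km = c(40, 40), bearing_sd = 0,
                    patch_radius_km = 5, patch_dwell_h = 2.5)
  fx <- simulate_tracks(cfg)
  mask <- simulate_landscape(cfg)$mask
  trips <- segment_trips(split(fx, fx$id)[[1]], mask)
  res <- ars_analysis(trips[[1]])
  expect_false(is.null(res$zones))
  main <- res$zones[which.max(res$zones$max_fpt_h), ]
  expect_equal(main$distance_to_colony_km, 40, tolerance = 2)
  # scale labels are ordered by descending radius
  if (nrow(res$scales) > 1)
    expect_true(all(diff(res$scales$radius) < 0))
})

test_that("sea trips below the mainland crossing distance are excluded", {
  tt <- data.frame(destination = c("sea", "sea", "sea", "inland", "mixed",
                                   "island"),
                   foraging_range_km = c(5, 7.8, 20, 10, 30, 2))
  out <- filter_sea_trips(tt)
  expect_equal(nrow(out), 3)
  expect_true(all(out$destination %in% c("sea", "inland")))
  expect_true(7.8 %in% out$foraging_range_km)   # inclusive bound retained
  expect_false(5 %in% out$foraging_range_km)
  expect_false("mixed" %in% out$destination)
})
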