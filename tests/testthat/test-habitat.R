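# Availability-versus-use selection, feeding spots, Monte-Carlo chi-squared.

test_that("proportional use reproduces the worked farmland ratios", {
  ht <- table_from_counts(farmland_availability(), farmland_use())
  r <- proportional_use(ht)
  expect_equal(round(r[["potato"]], 3), 17.000)
  expect_equal(round(r[["grassland"]], 3), 0.701)
  expect_equal(round(r[["corn"]], 3), 1.645)
  expect_true(is.na(r[["waste_disposal"]]))  # zero availability: undefined
  # equal shares give ratio 1
  ht2 <- table_from_counts(c(a = 50, b = 50), c(a = 5, b = 5))
  expect_equal(unname(proportional_use(ht2)), c(1, 1))
})

test_that("goodness-of-fit chi-squared matches the two-cell hand computation", {
  # per-habitat two-cell forms
  pot <- gof_chisq_mc(c(6, 32), c(12, 1280) / 1292, n_sim = 100, seed = 1)
  expect_equal(round(pot$statistic, 2), 91.20)
  gra <- gof_chisq_mc(c(17, 21), c(824, 468) / 1292, n_sim = 100, seed = 1)
  expect_equal(round(gra$statistic, 2), 5.96)
  crn <- gof_chisq_mc(c(12, 26), c(248, 1044) / 1292, n_sim = 100, seed = 1)
  expect_equal(round(crn$statistic, 2), 3.76)
  grp <- gof_chisq_mc(c(21, 17), c(276, 1016) / 1292, n_sim = 100, seed = 1)
  expect_equal(round(grp$statistic, 2), 26.00)
  # observation at expectation: statistic 0, simulated p = 1
  res <- gof_chisq_mc(c(25, 75), c(0.25, 0.75), n_sim = 500, seed = 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(gof_chisq_mc(c(1, 2), c(0.5, 0.6)), "sum to 1")
  expect_error(gof_chisq_mc(c(1, 2), c(1, 0)), "zero expected")
})

test_that("selection test covers grouped, per-habitat and overall forms", {
  ht <- table_from_counts(farmland_availability(), farmland_use())
  sel <- habitat_selection_test(ht, n_sim = 2000, seed = 5)
  per <- sel$per_habitat
  expect_equal(round(per$chisq[per$habitat == "potato"], 2), 91.20)
  expect_lt(per$p[per$habitat == "potato"], 0.001)
  expect_equal(round(per$chisq[per$habitat == "grassland"], 2), 5.96)
  expect_equal(round(sel$per_habitat$proportional_use[per$habitat == "corn"],
                     3), 1.645)
  # availability <= 4 or zero availability: no test run
  expect_true(is.na(per$chisq[per$habitat == "pea"]))
  expect_true(is.na(per$chisq[per$habitat == "waste_disposal"]))
  # grouped open vs ground-covering comparison
  expect_equal(round(attr(sel$grouped, "chisq"), 2), 26.00)
  expect_equal(round(sel$grouped$proportional_use, 3), c(2.587, 0.569))
  # use counts are conserved
  expect_equal(sum(ht$use), 38)
  expect_output(print(sel), "open vs ground-covering")
})

test_that("Monte-Carlo p converges to the exact multinomial tail", {
  # 3-category toy: enumerate all outcomes of multinomial(n = 12, p)
  p <- c(0.2, 0.3, 0.5); n <- 12
  obs <- c(6, 2, 4)
  e <- n * p
  stat_obs <- sum((obs - e)^2 / e)
  exact <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    cc <- n - a - b
    s <- sum((c(a, b, cc) - e)^2 / e)
    if (s >= stat_obs)
      exact <- exact + dmultinom(c(a, b, cc), prob = p)
  }
  res <- gof_chisq_mc(obs, p, n_sim = 100000, seed = 7)
  expect_lt(abs(res$p_value - exact), 0.01)
})

test_that("feeding spots require 30 min dwell in a 500-m cell", {
  cfg <- sim_config(seed = 2)
  ls <- simulate_landscape(cfg)
  mk_dwell_trip <- function(n_fixes, id = "b1") {
    # commute out, then n_fixes at 3-min spacing jittered inside one cell
    xj <- 0.1 + 0.05 * sin(seq_len(n_fixes))
    yj <- -15.1 - 0.05 * cos(seq_len(n_fixes))
    x <- c(0, 0, xj, 0, 0); y <- c(0, -8, yj, -8, 0)
    spd <- c(40, 40, rep(4, n_fixes), 40, 40)
    make_trip(x, y, speed = spd, id = id)
  }
  # 11 fixes spanning 30 min: exactly one spot
  spots <- detect_feeding_spots(list(mk_dwell_trip(11)), ls$grid, ls$mask)
  expect_equal(nrow(spots), 1)
  expect_gte(spots$dwell_min[1], 30)
  expect_gte(spots$n_fixes[1], 2)
  expect_false(is.na(spots$habitat[1]))
  expect_true(spots$primary[1])
  # 9 fixes spanning 24 min: none
  spots <- detect_feeding_spots(list(mk_dwell_trip(9)), ls$grid, ls$mask)
  expect_equal(nrow(spots), 0)
})

test_that("per-individual spot count is capped by seeded trip selection", {
  cfg <- sim_config(seed = 2)
  ls <- simulate_landscape(cfg)
  # 10 trips x 2 separated dwell cells each = 20 candidate spots
  mk_two_cell_trip <- function(k) {
    xj <- 0.1 + 0.05 * sin(1:11)
    x <- c(0, xj + k, xj + k + 2, 0)
    y <- c(0, rep(-15.1, 11), rep(-15.1, 11), 0)
    spd <- c(40, rep(4, 22), 40)
    make_trip(x[c(1, 2:12, 13:23, 24)], y, speed = spd, id = "b1")
  }
  trips <- lapply(seq(0, 27, by = 3), mk_two_cell_trip)
  all_spots <- detect_feeding_spots(trips, ls$grid, ls$mask,
                                    cap_per_individual = 100L)
  expect_equal(nrow(all_spots), 20)
  capped <- detect_feeding_spots(trips, ls$grid, ls$mask,
                                 cap_per_individual = 15L, seed = 9)
  expect_equal(nrow(capped), 15)
  again <- detect_feeding_spots(trips, ls$grid, ls$mask,
                                cap_per_individual = 15L, seed = 9)
  expect_identical(capped, again)
})

test_that("diet frequency of occurrence is per-pellet percentage", {
  m <- matrix(0, nrow = 50, ncol = 3,
              dimnames = list(NULL, c("grass", "fish", "eggs")))
  m[1:24, "grass"] <- 1
  m[, "fish"] <- 1
  fo <- diet_frequency(m)
  expect_equal(fo[["grass"]], 48.0)
  expect_equal(fo[["fish"]], 100)
  expect_equal(fo[["eggs"]], 0)
  expect_error(diet_frequency(m[0, ]), "at least one")
})
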