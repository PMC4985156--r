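# Availability-versus-use habitat selection on land: terrestrial feeding
# spots are dwell-based (>= 30 min within a 500 x 500 m cell at ground
# speeds), compared against a habitat-availability survey by proportional
# use ratios and goodness-of-fit chi-squared tests with Monte-Carlo p-values.

# Habitats with little or no vegetation cover (open soil): gulls reach the
# ground directly there, against ground-covering vegetation. Refuse sites
# (waste disposal) count as open ground.
open_ground_habitats <- function() {
  c("corn", "potato", "summer_wheat", "ploughed_soil",
    "construction_area", "water_body", "waste_disposal")
}

#' Detect terrestrial feeding spots from trips
#'
#' Mainland fixes with device speed at most `max_speed` (flight segments
#' excluded) are binned into square cells of `cell_km` anchored at the
#' colony's projected origin. A cell in which one trip's fixes span at
#' least `min_dwell_min` becomes a feeding spot (dwell measured
#' last-minus-first fix within the cell; set `contiguous = TRUE` to require
#' an unbroken run instead). Per individual, at most `cap_per_individual`
#' spots are retained by accumulating whole trips in seeded random order;
#' the most-dwelled spot of each trip is flagged `primary`.
#'
#' @param trips List of `forage_trip` objects.
#' @param grid A [habitat_grid()] supplying habitat labels.
#' @param mask A [landscape_mask()]; fixes must classify as mainland.
#' @param max_speed Maximum ground speed for feeding fixes (km/h).
#' @param min_dwell_min Minimum dwell per cell (minutes).
#' @param cell_km Cell edge (km).
#' @param cap_per_individual Maximum retained spots per individual.
#' @param seed Seed for the random trip selection under the cap.
#' @param contiguous Require an unbroken in-cell run of fixes.
#' @param origin_offset_km Grid-origin shift (km); spot counts can move by
#'   one under translation, so the anchoring is explicit and reported.
#' @return Data frame of feeding spots: `individual`, `trip`, `cell_id`,
#'   `lon`, `lat`, `dwell_min`, `n_fixes`, `habitat`, `primary`.
#' @export
detect_feeding_spots <- function(trips, grid, mask, max_speed = 10,
                                 min_dwell_min = 30, cell_km = 0.5,
                                 cap_per_individual = 15L, seed = 1L,
                                 contiguous = FALSE,
                                 origin_offset_km = c(0, 0)) {
  spots <- list()
  for (ti in seq_along(trips)) {
    tr <- trips[[ti]]
    f <- tr$fixes
    cls <- classify_points(mask, f$lon, f$lat, use_colony = TRUE)
    use <- f$speed_kmh <= max_speed & cls == "mainland"
    if (!any(use)) next
    g <- f[use, , drop = FALSE]
    xy <- project_local(g$lon, g$lat, tr$colony)
    ix <- floor((xy[, 1] - origin_offset_km[1]) / cell_km)
    iy <- floor((xy[, 2] - origin_offset_km[2]) / cell_km)
    cell <- paste(ix, iy, sep = ":")
    for (cid in unique(cell)) {
      in_cell <- cell == cid
      if (sum(in_cell) < 2L) next
      dwell <- if (contiguous) {
        runs <- rle(in_cell)
        re <- cumsum(runs$lengths); rs <- re - runs$lengths + 1L
        spans <- vapply(which(runs$values), function(k) {
          as.numeric(difftime(g$timestamp[re[k]], g$timestamp[rs[k]],
                              units = "mins"))
        }, numeric(1))
        max(spans)
      } else {
        as.numeric(difftime(max(g$timestamp[in_cell]),
                            min(g$timestamp[in_cell]), units = "mins"))
      }
      if (dwell < min_dwell_min) next
      lon_c <- mean(g$lon[in_cell]); lat_c <- mean(g$lat[in_cell])
      spots[[length(spots) + 1L]] <- data.frame(
        individual = tr$individual, trip = ti, cell_id = cid,
        lon = lon_c, lat = lat_c, dwell_min = dwell,
        n_fixes = sum(in_cell),
        habitat = habitat_at(grid, lon_c, lat_c),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(spots))
    return(data.frame(individual = character(), trip = integer(),
                      cell_id = character(), lon = numeric(), lat = numeric(),
                      dwell_min = numeric(), n_fixes = integer(),
                      habitat = character(), primary = logical()))
  sp <- do.call(rbind, spots)
  key <- paste(sp$individual, sp$trip)
  sp$primary <- stats::ave(sp$dwell_min, key,
                           FUN = function(v) v == max(v)) > 0

  # seeded cap: accumulate whole trips in random order, truncate at the cap
  set.seed(seed)
  kept <- list()
  for (id in unique(sp$individual)) {
    s <- sp[sp$individual == id, , drop = FALSE]
    if (nrow(s) > cap_per_individual) {
      trips_of <- sample(unique(s$trip))
      s <- s[order(match(s$trip, trips_of)), , drop = FALSE]
      s <- s[seq_len(cap_per_individual), , drop = FALSE]
    }
    kept[[id]] <- s
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

#' Availability-versus-use habitat table
#'
#' @param survey Data frame `segment_id`, `habitat` (availability survey).
#' @param spots Feeding spots from [detect_feeding_spots()], or a data
#'   frame with a `habitat` column; `primary_only` restains the analysis
#'   to the most-dwelled spot per trip.
#' @param primary_only Use only primary spots (default `TRUE`).
#' @return A `habitat_table` data frame: `habitat`, `availability`, `use`,
#'   sorted by decreasing availability, with totals as attributes.
#' @export
habitat_table <- function(survey, spots, primary_only = TRUE) {
  stopifnot(all(c("habitat") %in% names(survey)))
  use_h <- spots$habitat
  if (primary_only && "primary" %in% names(spots))
    use_h <- spots$habitat[spots$primary]
  use_h <- use_h[!is.na(use_h)]
  habitats <- union(unique(survey$habitat), unique(use_h))
  avail <- table(factor(survey$habitat, levels = habitats))
  use <- table(factor(use_h, levels = habitats))
  out <- data.frame(habitat = habitats,
                    availability = as.integer(avail),
                    use = as.integer(use))
  out <- out[order(-out$availability), ]
  rownames(out) <- NULL
  structure(out, class = c("habitat_table", "data.frame"),
            total_availability = sum(out$availability),
            total_use = sum(out$use))
}

#' Proportional habitat use
#'
#' The ratio of the use share to the availability share per habitat:
#' greater than 1 indicates relative preference, below 1 avoidance.
#' Undefined (NA) for habitats with zero availability.
#'
#' @param table A [habitat_table()].
#' @return Named numeric vector of ratios.
#' @export
proportional_use <- function(table) {
  at <- sum(table$availability); ut <- sum(table$use)
  if (at == 0 || ut == 0) stop("zero total availability or use")
  ratio <- (table$use / ut) / (table$availability / at)
  ratio[table$availability == 0] <- NA_real_
  stats::setNames(ratio, table$habitat)
}

#' Goodness-of-fit chi-squared with Monte-Carlo p-value
#'
#' `X2 = sum (obs_i - n p_i)^2 / (n p_i)` against expected proportions
#' `p`, with the p-value simulated from `n_sim` multinomial tables under
#' the null and the add-one estimator
#' `p = (1 + #(X2_sim >= X2_obs)) / (n_sim + 1)` (never exactly zero).
#'
#' @param observed Non-negative integer counts.
#' @param expected_proportions Probabilities summing to 1; all positive
#'   (exclude zero-availability categories upstream).
#' @param n_sim Number of Monte-Carlo replicates.
#' @param seed Seed for the multinomial draws.
#' @return List with `statistic`, `p_value`, `n_sim`, `df` (categories - 1).
#' @export
gof_chisq_mc <- function(observed, expected_proportions, n_sim = 10000L,
                         seed = 1L) {
  p <- expected_proportions
  if (abs(sum(p) - 1) > 1e-9) stop("expected proportions must sum to 1")
  if (any(p <= 0)) stop("zero expected proportion: exclude the category upstream")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (length(observed) != length(p)) stop("length mismatch")
  n <- sum(observed)
  e <- n * p
  stat <- sum((observed - e)^2 / e)
  set.seed(seed)
  sims <- stats::rmultinom(n_sim, n, p)
  sim_stat <- colSums((sims - e)^2 / e)
  list(statistic = stat,
       p_value = (1 + sum(sim_stat >= stat)) / (n_sim + 1),
       n_sim = n_sim, df = length(p) - 1L)
}

#' Habitat-selection tests on an availability-versus-use table
#'
#' Per habitat with availability above `min_avail`, a two-cell (habitat
#' versus rest) goodness-of-fit chi-squared with Monte-Carlo p-value; plus
#' the grouped comparison of open-ground versus ground-covering vegetation,
#' and the overall multi-category test over habitats with non-zero
#' availability. Habitats with zero availability but recorded use are
#' reported with undefined ratio and excluded from testing.
#'
#' @param table A [habitat_table()].
#' @param open_habitats Habitat labels counted as open ground.
#' @param n_sim Monte-Carlo replicates per test.
#' @param seed Seed (each test derives its own stream deterministically).
#' @param min_avail Tests only run for habitats with availability above
#'   this count.
#' @return A `habitat_selection` object: `per_habitat` data frame
#'   (`habitat`, `availability`, `feeding_spots`, `proportional_use`,
#'   `chisq`, `p`), `grouped` data frame for the open versus covered
#'   comparison, and `overall` (list, multi-category test with a note on
#'   its construction).
#' @export
habitat_selection_test <- function(table, open_habitats = open_ground_habitats(),
                                   n_sim = 10000L, seed = 1L, min_avail = 4L) {
  at <- sum(table$availability); ut <- sum(table$use)
  ratios <- proportional_use(table)
  per <- data.frame(habitat = table$habitat,
                    availability = table$availability,
                    feeding_spots = table$use,
                    proportional_use = as.numeric(ratios),
                    chisq = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(per))) {
    a <- per$availability[i]
    if (a <= min_avail || a == at) next
    res <- gof_chisq_mc(c(per$feeding_spots[i], ut - per$feeding_spots[i]),
                        c(a, at - a) / at, n_sim = n_sim, seed = seed + i)
    per$chisq[i] <- res$statistic
    per$p[i] <- res$p_value
  }

  open <- table$habitat %in% open_habitats
  g_avail <- c(open = sum(table$availability[open]),
               covered = sum(table$availability[!open]))
  g_use <- c(open = sum(table$use[open]), covered = sum(table$use[!open]))
  g_res <- gof_chisq_mc(g_use, g_avail / at, n_sim = n_sim, seed = seed + 1000L)
  grouped <- data.frame(group = c("no_little_vegetation",
                                  "ground_covering_vegetation"),
                        availability = as.integer(g_avail),
                        feeding_spots = as.integer(g_use),
                        proportional_use = (g_use / ut) / (g_avail / at),
                        row.names = NULL)
  attr(grouped, "chisq") <- g_res$statistic
  attr(grouped, "p") <- g_res$p_value

  nz <- table$availability > 0
  o_res <- gof_chisq_mc(table$use[nz], table$availability[nz] / at,
                        n_sim = n_sim, seed = seed + 2000L)
  overall <- list(statistic = o_res$statistic, p_value = o_res$p_value,
                  df = o_res$df,
                  note = paste("multinomial goodness-of-fit over habitats",
                               "with non-zero availability; zero-availability",
                               "habitats excluded"))
  structure(list(per_habitat = per, grouped = grouped, overall = overall,
                 n_sim = n_sim, min_avail = min_avail),
            class = "habitat_selection")
}

#' @export
print.habitat_selection <- function(x, ...) {
  cat("Habitat selection (availability vs use)\n")
  cat(sprintf("  open vs ground-covering: X2 = %.2f, p = %.4g\n",
              attr(x$grouped, "chisq"), attr(x$grouped, "p")))
  g <- x$grouped
  for (i in seq_len(nrow(g)))
    cat(sprintf("    %-28s avail %4d  spots %2d  ratio %.3f\n",
                g$group[i], g$availability[i], g$feeding_spots[i],
                g$proportional_use[i]))
  cat(sprintf("  overall (%d df): X2 = %.2f, p = %.4g\n",
              x$overall$df, x$overall$statistic, x$overall$p_value))
  p <- x$per_habitat
  cat("  per habitat:\n")
  for (i in seq_len(nrow(p)))
    cat(sprintf("    %-18s avail %4d  spots %2d  ratio %s  X2 %s  p %s\n",
                p$habitat[i], p$availability[i], p$feeding_spots[i],
                ifelse(is.na(p$proportional_use[i]), "  -  ",
                       sprintf("%6.3f", p$proportional_use[i])),
                ifelse(is.na(p$chisq[i]), "  -  ",
                       sprintf("%6.2f", p$chisq[i])),
                ifelse(is.na(p$p[i]), "-", sprintf("%.3f", p$p[i]))))
  invisible(x)
}

#' Frequency of occurrence of diet items in pellets
#'
#' @param incidence Pellet-by-item incidence table (matrix or data frame of
#'   0/1 or logical; rows are pellets). Items may co-occur, so frequencies
#'   can sum to more than 100.
#' @return Named numeric vector: percentage of pellets containing each item,
#'   sorted decreasing.
#' @export
diet_frequency <- function(incidence) {
  m <- as.matrix(incidence)
  if (nrow(m) < 1L) stop("need at least one pellet")
  storage.mode(m) <- "numeric"
  fo <- 100 * colMeans(m > 0)
  sort(fo, decreasing = TRUE)
}
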