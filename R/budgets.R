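#' Diel activity budget: sea versus land use by local hour
#'
#' Pools all trip fixes, classifies them against the mask (open sea and
#' tidal flats count as sea; mainland as land; colony-buffer and island
#' fixes are excluded), computes the land share per individual and local
#' hour, and averages across individuals. Local time is UTC plus a fixed
#' offset (CEST = +2) for reproducibility.
#'
#' @param trips List of `forage_trip` objects.
#' @param mask A [landscape_mask()].
#' @param utc_offset Hours added to UTC for the local clock.
#' @return Data frame with one row per hour 0-23: `hour`,
#'   `n_individuals`, `land_share_mean`, `land_share_se`,
#'   `sea_share_mean`. Hours with no fixes carry `n_individuals = 0` and
#'   `NA` shares (flagged, excluded from means).
#' @export
diel_budget <- function(trips, mask, utc_offset = 2) {
  per_fix <- budget_fix_table(trips, mask, utc_offset)
  per_fix$bin <- per_fix$hour
  budget_aggregate(per_fix, bins = 0:23, bin_name = "hour")
}

#' Weekday activity budget: sea versus land use by day of week
#'
#' Same construction as [diel_budget()] but aggregated over local day of
#' week (1 = Monday ... 7 = Sunday), reflecting weekly cycles in human
#' activity (fishing, field work) that structure foraging opportunity.
#'
#' @inheritParams diel_budget
#' @return Data frame with one row per weekday: `weekday`,
#'   `n_individuals`, `land_share_mean`, `land_share_se`,
#'   `sea_share_mean`.
#' @export
weekday_budget <- function(trips, mask, utc_offset = 2) {
  per_fix <- budget_fix_table(trips, mask, utc_offset)
  per_fix$bin <- per_fix$weekday
  budget_aggregate(per_fix, bins = 1:7, bin_name = "weekday")
}

budget_fix_table <- function(trips, mask, utc_offset) {
  if (!length(trips)) stop("no trips supplied")
  rows <- lapply(trips, function(tr) {
    f <- tr$fixes
    cls <- classify_points(mask, f$lon, f$lat, use_colony = TRUE)
    side <- ifelse(cls %in% c("sea", "tidal_flat"), "sea",
                   ifelse(cls == "mainland", "land", NA_character_))
    keep <- !is.na(side)
    lt <- f$timestamp[keep] + utc_offset * 3600
    data.frame(individual = tr$individual,
               side = side[keep],
               hour = as.integer(format(lt, "%H", tz = "UTC")),
               weekday = as.integer(format(lt, "%u", tz = "UTC")))
  })
  do.call(rbind, rows)
}

budget_aggregate <- function(per_fix, bins, bin_name) {
  out <- data.frame(bin = bins, n_individuals = 0L,
                    land_share_mean = NA_real_, land_share_se = NA_real_,
                    sea_share_mean = NA_real_)
  for (i in seq_along(bins)) {
    sub <- per_fix[per_fix$bin == bins[i], ]
    if (nrow(sub) == 0L) next
    shares <- tapply(sub$side == "land", sub$individual, mean)
    shares <- shares[!is.na(shares)]
    out$n_individuals[i] <- length(shares)
    out$land_share_mean[i] <- mean(shares)
    out$land_share_se[i] <- if (length(shares) > 1)
      stats::sd(shares) / sqrt(length(shares)) else NA_real_
    out$sea_share_mean[i] <- 1 - mean(shares)
  }
  names(out)[1] <- bin_name
  out
}

#' Two-sided F test for equality of variances
#'
#' Compares the variability of a trip characteristic between destination
#' classes (e.g. sea versus inland trip durations): `F = var(a) / var(b)`
#' with a two-sided p-value from the F distribution on
#' `(n_a - 1, n_b - 1)` degrees of freedom.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `statistic` (F), `df` (length 2), and `p_value`.
#' @export
variance_ratio_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(b) == 0) stop("zero variance in denominator sample")
  ht <- stats::var.test(a, b)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
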