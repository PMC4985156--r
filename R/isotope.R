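# Stable-isotope habitat-use analysis: delta notation, lipid normalization,
# trophic discrimination, proportion-of-foraging-at-sea from tracks, and the
# mixing regression of delta values on that proportion. Increasing delta13C
# indicates a more marine origin of prey; delta15N indexes trophic level.

#' Isotope ratio in delta notation (permil)
#'
#' `deltaX = (R_sample / R_standard - 1) * 1000`, where R is the
#' heavy-to-light isotope ratio (13C:12C versus V-PDB, 15N:14N versus air
#' N2).
#'
#' @param r_sample,r_standard Positive isotope ratios.
#' @return Delta value(s) in permil.
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be positive")
  (r_sample / r_standard - 1) * 1000
}

#' Lipid normalization of delta13C
#'
#' Corrects the lipid bias of delta13C in aquatic animals using the tissue
#' C:N mass ratio: `d13C_normalized = d13C - 3.32 + 0.99 * C:N`. Intended
#' for plasma (lipid-rich); the formula is uncapped, so a warning is issued
#' for C:N above `warn_above`, where the additive correction grows beyond
#' the range the relation was calibrated on.
#'
#' @param d13c delta13C values (permil).
#' @param c_to_n C:N mass ratio(s), > 0.
#' @param warn_above Warn when C:N exceeds this value.
#' @return Normalized delta13C (permil).
#' @export
lipid_normalize <- function(d13c, c_to_n, warn_above = 10) {
  if (any(c_to_n <= 0)) stop("C:N ratio must be positive")
  if (any(c_to_n > warn_above))
    warning("C:N ratio above ", warn_above,
            ": lipid normalization extrapolates far outside calibration")
  d13c - 3.32 + 0.99 * c_to_n
}

#' Trophic discrimination correction
#'
#' Subtracts the diet-to-blood discrimination factor (2.4 permil for
#' delta15N, 0.7 permil for delta13C, averages for aquatic birds on aquatic
#' diets) to place consumer values on the prey scale. The result carries a
#' `discriminated` attribute; applying the correction twice is an error
#' unless `force = TRUE`.
#'
#' @param delta Consumer delta values (permil).
#' @param isotope `"C"` or `"N"`.
#' @param force Allow re-application.
#' @return Corrected delta values with attribute `discriminated = TRUE`.
#' @export
apply_discrimination <- function(delta, isotope = c("C", "N"), force = FALSE) {
  isotope <- match.arg(isotope)
  if (isTRUE(attr(delta, "discriminated")) && !force)
    stop("discrimination already applied; use force = TRUE to re-apply")
  out <- delta - switch(isotope, C = 0.7, N = 2.4)
  attr(out, "discriminated") <- TRUE
  out
}

#' Proportion of foraging at sea per individual
#'
#' The fraction of trip fixes (colony-buffer fixes excluded) that classify
#' as marine (open sea or tidal flat) by the mask, per individual. An
#' individual with no off-colony trip fixes is excluded with a warning.
#'
#' @param trips List of `forage_trip` objects.
#' @param mask A [landscape_mask()].
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
sea_fraction <- function(trips, mask) {
  if (!length(trips)) stop("no trips supplied")
  counts <- list()
  for (tr in trips) {
    f <- tr$fixes
    cls <- classify_points(mask, f$lon, f$lat, use_colony = TRUE)
    off <- cls != "colony"
    sea <- cls %in% c("sea", "tidal_flat")
    prev <- counts[[tr$individual]]
    if (is.null(prev)) prev <- c(sea = 0, total = 0)
    counts[[tr$individual]] <- prev + c(sea = sum(sea & off),
                                        total = sum(off))
  }
  out <- vapply(counts, function(ct) {
    if (ct["total"] == 0) NA_real_ else unname(ct["sea"] / ct["total"])
  }, numeric(1))
  if (anyNA(out)) {
    warning("individual(s) with no off-colony fixes excluded: ",
            paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Regress isotope values on the proportion of foraging at sea
#'
#' Ordinary least-squares regressions of delta13C and delta15N on the
#' per-individual marine foraging fraction, per tissue. Under two-endmember
#' mixing the slope estimates `delta_sea - delta_land` on the consumer
#' scale. Plasma delta13C is lipid-normalized first by default (plasma is
#' the lipid-rich fraction); set `normalize_plasma = FALSE` for raw values,
#' `normalize_all = TRUE` to extend normalization to red blood cells.
#'
#' @param samples Data frame with columns `individual_id`, `tissue`,
#'   `d13C`, `d15N`, `c_to_n`.
#' @param fractions Named vector of marine fractions (names match
#'   `individual_id`).
#' @param normalize_plasma Lipid-normalize plasma delta13C.
#' @param normalize_all Also normalize non-plasma tissues.
#' @return An `isotope_mixing` data frame: one row per tissue x isotope
#'   with `slope`, `intercept`, `se_slope`, `t`, `p`, `df`, `n`.
#' @export
isotope_regression <- function(samples, fractions, normalize_plasma = TRUE,
                               normalize_all = FALSE) {
  need <- c("individual_id", "tissue", "d13C", "d15N", "c_to_n")
  stopifnot(all(need %in% names(samples)))
  rows <- list()
  for (tis in unique(samples$tissue)) {
    sub <- samples[samples$tissue == tis, ]
    x <- fractions[match(sub$individual_id, names(fractions))]
    ok <- !is.na(x)
    sub <- sub[ok, ]; x <- x[ok]
    if (nrow(sub) < 3L)
      stop("need at least 3 matched individuals for tissue ", tis)
    if (stats::var(x) == 0)
      stop("zero variance in sea fractions: regression undefined")
    d13c <- sub$d13C
    if (normalize_all || (normalize_plasma && tis == "plasma"))
      d13c <- lipid_normalize(d13c, sub$c_to_n)
    for (iso in c("d13C", "d15N")) {
      y <- if (iso == "d13C") d13c else sub$d15N
      fit <- stats::lm(y ~ x)
      cf <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tis, isotope = iso,
        slope = cf[2, 1], intercept = cf[1, 1], se_slope = cf[2, 2],
        t = cf[2, 3], p = cf[2, 4],
        df = fit$df.residual, n = nrow(sub))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("isotope_mixing", "data.frame")
  out
}

#' @export
print.isotope_mixing <- function(x, ...) {
  cat("Isotope mixing regressions (delta ~ proportion at sea)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-16s %-5s slope %6.2f (SE %4.2f)  t = %5.2f, p = %.3g, df = %d\n",
                x$tissue[i], x$isotope[i], x$slope[i], x$se_slope[i],
                x$t[i], x$p[i], x$df[i]))
  invisible(x)
}
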