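# dualforage

Movement-ecology tools for the *dual* foraging strategy of a
central-place-foraging seabird that exploits both the open sea and inland
farmland from an island colony. Given GPS logger fixes (one row every few
minutes: position and device speed), the package

- segments **foraging trips** against a colony buffer and computes trip
  metrics — duration, foraging range, total distance, straightness, and a
  destination class (sea / inland / mixed / island) from where the bird
  dwelt;
- detects **area-restricted search (ARS)** by First-Passage Time: the FPT
  at a path point is the time to cross a circle of radius *r* centred
  there, and peaks of var(log FPT) over *r* locate the spatial scale of
  search; zones are delineated by thresholding the FPT series at the peak
  scale;
- tests **terrestrial habitat selection** by comparing habitat
  availability (survey segments) with use (dwell-based feeding spots:
  ≥ 30 min in a 500 × 500 m cell at ground speeds ≤ 10 km h⁻¹), via
  proportional-use ratios and goodness-of-fit χ² with Monte-Carlo
  p-values;
- relates **stable isotopes to habitat use**: δ¹³C/δ¹⁵N per tissue
  (δ notation, lipid normalization δ¹³C − 3.32 + 0.99·C:N, trophic
  discrimination 0.7‰/2.4‰) regressed on the per-individual proportion
  of GPS fixes at sea, the two-endmember mixing view of a marine versus
  terrestrial diet;
- and ships a seeded **synthetic generator** (tracks with embedded ARS
  patches, land/sea mask, habitat grid and survey, isotope samples) so the
  whole pipeline is testable end to end without deployed loggers.

Core quantities, in the field's notation: straightness
`S = 2·range / total distance` (1 for a perfectly direct out-and-back
trip); FPT(r) with ARS scale `r* = argmax_r var(log FPT(r))` over the
two-step grids 1–50 km (every 1 km) and 0.1–10 km (every 0.1 km);
proportional use `(use_h/use_tot) / (avail_h/avail_tot)`; goodness-of-fit
`χ² = Σ (o_i − n p_i)² / (n p_i)` with simulated
`p = (1 + #{χ²_sim ≥ χ²_obs}) / (n_sim + 1)`.

## Worked example

```r
library(dualforage)

cfg   <- sim_config(seed = 42, n_individuals = 6, n_trips_per_individual = 5,
                    p_sea = 0.5)
fixes <- simulate_tracks(cfg)
land  <- simulate_landscape(cfg)

trips <- unlist(lapply(split(fixes, fixes$id), segment_trips,
                       mask = land$mask), recursive = FALSE)
tt <- trips_table(trips, land$mask)
summarize_trips(tt)[, c("destination", "n", "pct",
                        "foraging_range_km_mean", "straightness_mean")]
#>   destination  n pct foraging_range_km_mean straightness_mean
#> 1         sea 18  60                   41.4             0.868
#> 2      inland 12  40                   19.1             0.788
#> 3     overall 30 100                   32.5             0.836

ars_analysis(trips[[2]])
#> ARS analysis: bird01
#>   1st scale: r* = 3 km
#>   2nd scale: r* = 2.4 km
#>   3rd scale: r* = 0.6 km
#>   zones: 4

fr  <- sea_fraction(trips, land$mask)    # proportion of fixes at sea
iso <- simulate_isotopes(fr, cfg)
isotope_regression(iso, fr)
#> Isotope mixing regressions (delta ~ proportion at sea)
#>   plasma           d13C  slope   8.61 (SE 0.78)  t = 11.05, p = 0.000382, df = 4
#>   plasma           d15N  slope   6.47 (SE 1.27)  t =  5.09, p = 0.00702, df = 4
#>   red_blood_cells  d13C  slope   8.15 (SE 1.17)  t =  6.95, p = 0.00225, df = 4
#>   red_blood_cells  d15N  slope   5.79 (SE 1.37)  t =  4.22, p = 0.0135, df = 4
```

The trip summary says 18 of 30 trips (60%) dwelt at sea; sea trips reach
about twice as far as inland ones. The ARS analysis of one trip finds up
to three nested search scales (labelled 1st–3rd by descending radius).
The isotope slopes estimate the marine-minus-terrestrial endmember
difference (9‰ for δ¹³C, 6‰ for δ¹⁵N in the generator) and `df = n − 2`
with one sample per bird and tissue.

The pipeline version of the same analysis, driven by a YAML config:

```sh
Rscript inst/cli/forage.R all --config inst/extdata/demo_config.yml --outdir out/
```

writes `trips.csv`, `diel_budget.csv`, `ars_zones.csv` (+ GeoJSON),
`feeding_spots.csv`, `habitat_selection.csv`, `isotope_regression.csv` and
a `summary.txt` traceable to those tables.

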