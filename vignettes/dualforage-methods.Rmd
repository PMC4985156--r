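---
title: "Methods: trip segmentation, first-passage time and habitat-use inference in dualforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trip segmentation, first-passage time and habitat-use inference in dualforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualforage)
```

`dualforage` analyses GPS-logger data from a central-place forager — a
large gull breeding on an island — that splits its foraging between the
open sea and inland farmland. This vignette is the package's own account
of the models and procedures, the parameters that matter, and the design
choices made where the underlying field methodology left them open.

## Geometry

All distances are great-circle (haversine) on the WGS84 mean sphere,
R = 6371.0088 km. The study area spans well under 100 km, where
ellipsoidal corrections are an order of magnitude below GPS fix error.
Planar constructions (feeding-spot cells, the synthetic landscape, FPT
distance computations) use a local azimuthal-equidistant projection
centred on the colony: distances from the colony are exact by
construction and inter-point distortion at these ranges is negligible.
Local clock time is UTC plus a fixed offset (CEST, +2) rather than a
timezone database, for bit-reproducibility.

## Trip segmentation and metrics

A foraging trip is a maximal run of fixes farther than `buffer_km`
(default 0.5 km) from the colony, extended to the bounding
buffer-crossing fixes, and retained if it spans at least `min_duration_h`
(default 0.5 h — the shortest credible foraging excursion in this system;
the raw-data criterion behind "clearly led away from the colony" is
judgement-based, so both values are explicit parameters). Metrics per
trip: duration; foraging range (maximum colony distance); total distance
(sum of great-circle legs); straightness `2·range/total`, capped at 1 for
complete trips where resampling noise can push it marginally above.

Destination classes are decided by *dwell* fixes — device speed below
10 km h⁻¹ outside the colony buffer, reusing the terrestrial feeding
filter. A trip is `mixed` when the marine and mainland sides each hold at
least 10% of dwell fixes (the threshold is a parameter; no published rule
exists), `island` when dwell occurs only on islands, otherwise the
majority side. Tidal-flat dwell counts to the marine side: the classes of
interest are sea/inland, and flats are a (rarely used) marine-edge
habitat here. A trip with no dwell fixes is classed by its most distant
fix.

The diel and weekday budgets compute, per individual and local-hour (or
weekday) bin, the share of trip fixes over mainland versus sea, then
average across individuals with a standard error; empty bins are flagged
and excluded. Variance comparisons between destination classes use the
two-sided F ratio test (`var.test`); the linear-mixed-model comparisons
published for such data are deliberately out of scope — only the variance
test is reproducible without the raw random-effects structure.

## First-passage time and ARS

FPT at a path point is the time between the last entry into and first
exit from a circle of radius *r* centred there. Before FPT analysis a
trip is preprocessed:

1. **Rest-bout removal.** Maximal runs of fixes with device speed below
   3 km h⁻¹ (resting/preening on water or ground) collapse to a single
   point at the run's start, and the bout's duration is excised from
   subsequent timestamps. Drift during rest otherwise creates spurious
   sub-100-m ARS that masks the scales of interest. Excision (rather than
   keeping the elapsed time) makes residence in a zone measure *active*
   search; at most one fix interval of bout time survives at the collapse
   point.
2. **Resampling** at a constant 0.1-km along-path spacing with linearly
   interpolated timestamps, so evaluation points represent distance, not
   sampling rate.

Circle crossings are located by linear interpolation of the
distance-to-centre function along segments — deterministic, and exactly
reproducible by an independent brute-force crossing search (the test
suite asserts bit-identical agreement). Implementation detail: per
evaluation point the running maximum of the distance series is
non-decreasing, so the crossing segment for every radius is found by
binary search after a single scan; FPT is undefined (never zero-filled)
where the path starts or ends inside the circle, and is monotone
non-decreasing in *r* wherever defined.

The ARS scale is read from the variance of log(FPT) (natural log; the
peak location is base-invariant) over two nested grids: 1–50 km every
1 km along the path, and 0.1–10 km every 0.1 km. Local maxima of the
variance curve are candidate scales; up to three distinct peak radii
(highest variance first) are kept per trip and labelled 1st/2nd/3rd by
*descending* radius, the coarsest scale first — the labelling rule is an
assumption, as the source methodology never states one.

**Thresholding.** Published practice sets the FPT threshold "by
inspecting the frequency distribution" at r*. For reproducibility the
package automates this subjective step: an Otsu two-class split of
log(FPT) (threshold maximising between-class variance), falling back to
the 75th percentile when the best split's separability η² is below 0.5 —
i.e. when the distribution looks unimodal and a two-class story is not
supported. A dip-type unimodality test would serve the same role; the
Otsu separability criterion was chosen because it reuses the split
already computed and has a transparent 0–1 scale. Contiguous
above-threshold runs become zones, each reporting entry time, maximum FPT
(maximum residence, in **hours** — the day-scaled figures sometimes
printed for such tables are inconsistent with an hour-scale text, and
this package reports hours throughout), the position of the maximum, and
its distance to the colony.

For land–sea comparisons, sea trips must reach at least 7.8 km range
(inclusive — "at least") — the direct over-water distance to the mainland
coast — and mixed/island trips are excluded, so both habitats are
compared over equal minimum commuting effort.

## Habitat selection on land

Feeding spots: mainland fixes at speeds ≤ 10 km h⁻¹ binned into 500-m
cells anchored at the colony's projected origin (the anchor is explicit
and configurable because spot counts can shift by ±1 cell under grid
translation); a cell where one trip's fixes span ≥ 30 min becomes a spot.
Dwell is last-minus-first fix in the cell (gaps tolerated); a
contiguous-run mode is available since "spent at least 30 min" is
ambiguous between cumulative and unbroken. Per individual at most 15
spots are kept, accumulating whole trips in seeded random order and
truncating at the cap; the most-dwelled spot per trip is flagged
`primary` and selection analyses use primary spots only.

Availability (survey segment counts) versus use (spot counts) is tested
by goodness-of-fit χ² with Monte-Carlo p-values (10,000 multinomial
replicates; add-one estimator, so p is never exactly 0): per habitat as a
two-cell habitat-versus-rest test (only for availability > 4), as a
grouped open-ground versus ground-covering-vegetation comparison (refuse
sites count as open ground — required for the grouped use counts to
partition as published), and as an overall multi-category test over
habitats with non-zero availability. Zero-availability habitats with
recorded use are reported with undefined ratio and excluded from testing.
The overall multi-category statistic is construction-dependent: the
goodness-of-fit form implemented here reproduces every per-habitat and
grouped statistic exactly but *not* the published pooled all-habitat
figure, whose exact construction (pooling and the zero-availability
category) is unstated; the package documents rather than imitates it.

## Isotopes

δ notation: `δX = (R_sample/R_standard − 1) × 1000` (‰, V-PDB for
carbon, air N₂ for nitrogen). Plasma δ¹³C is lipid-normalized with
`δ¹³C − 3.32 + 0.99·C:N` (plasma is the lipid-rich fraction; a flag
extends normalization to red cells); the formula is uncapped, so C:N
above 10 triggers a warning. Trophic discrimination (0.7‰ C, 2.4‰ N) is
subtracted explicitly and never silently; the result carries a guard
attribute so double application errors. Order of operations is fixed:
normalize, then discriminate.

The habitat-use link is ordinary least squares of δ on the proportion of
off-colony trip fixes classified as marine, per tissue × isotope, with
`t = slope/SE` on `n − 2` df. Under two-endmember mixing the slope
estimates `δ_sea − δ_land`. Plasma integrates days and red cells weeks,
so with real data the marine fraction should be computed over each
tissue's integration window; the synthetic generator draws both tissues
from one mixing line, and the package computes one whole-deployment
fraction.

## The synthetic generator

`sim_config()` defaults define the emulated study conditions: 8
individuals, 13 trips each, fixes every 3 min, P(sea trip) = 0.481, sea
trips bearing ≈ 330°, inland trips ≈ 180° and confined to a 05:00–21:30
local daylight window, a mainland coast 7.8 km south of the island
colony, a habitat mix matching a grassland-dominated arable survey of
1,292 segments, and isotope endmembers (−26/−17‰ δ¹³C, 8/14‰ δ¹⁵N
land/sea) with 0.5‰ noise. Commuting flight is 40 km h⁻¹ — an assumption,
since no flight-speed distribution is available for these loggers — as
near-straight correlated walk legs (wrapped-Cauchy turning,
concentration 0.97) steered at the destination. In-patch search is
low-concentration CRW legs between waypoints drawn uniformly over the
patch disc, so the *realised* search footprint matches the nominal patch
radius — with a locally diffusing walk the footprint stays well inside
the boundary and the configured radius would not be the true ARS scale.
Device speed is the true simulated speed plus N(0, 0.5 km h⁻¹) error.
Each individual draws from a stream seeded `seed + index`; equal
configurations are byte-identical.

What the generator does *not* emulate: tides, wind drift,
vessel-following at sea, habitat-dependent patch placement on land (spots
land on random parcels, so selection tests on synthetic data are null by
construction — passing tests demonstrate the machinery, not preference),
or tissue-specific isotope turnover. Results on synthetic data therefore
validate the algorithms, not behavioural conclusions.

## Verification experiments and problem sizes

The test suite and `scripts/acceptance.R` run, among others:

- exact worked examples on the published availability/use counts
  (ratios 17.000/0.701/1.645/2.587/0.569; χ² 91.20/5.96/3.76/26.00);
- FPT against the closed form 2r/v on straight constant-speed paths
  (error < spacing/v) and bit-exact agreement with a brute-force oracle
  on 50 random 200-point fixtures;
- ARS scale recovery: 20 seeded single-trip simulations per patch radius
  R ∈ {2, 5, 10} km, patch 40 km offshore, dwell max(1.5, R) h —
  residence scaling with patch size, in line with multi-hour trips and
  sub-day zone residence — asserting the median top variance-peak radius
  lies in [R/2, 2R];
- isotope slope recovery over 200 replicates of 50 individuals (≥ 90%
  within 2 SE of the generating slope; exact when noise-free);
- Monte-Carlo p against the exact multinomial tail on an enumerable
  3-category toy (n = 12; |Δp| < 0.01 at 100,000 replicates).

These sizes keep the full suite under a minute on one core while leaving
the stochastic checks comfortably away from their acceptance margins.

## Known limitations

- The FPT threshold automation is a reproducible stand-in for a
  judgement call; different reasonable rules shift zone boundaries
  (though rarely zone counts) for weakly bimodal FPT distributions.
- Dwell-based destination classes depend on the device speed field;
  loggers without speed would need speed derived from positions first.
- `read_grid_geojson()` reconstructs a colony-anchored grid written by
  this package; arbitrary external parcel maps should be rasterised to
  the grid format upstream.
- Straightness of incomplete trips (logger gaps at the colony) is
  reported uncapped and can exceed 1; filter on `complete` before
  comparing.
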