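---
title: "Validating gridded population rasters with resettlement ground truth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating gridded population rasters with resettlement ground truth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgridval)
```

## The validation model

The package compares, reservoir by reservoir, two numbers:

* `P_reported` — the number of people a national dam authority reports as
  resettled from a reservoir footprint, typically from ground surveys during
  dam planning and construction. These counts are independent of population
  censuses and of the gridded products being evaluated, which is what makes
  them usable as ground truth.
* `P_predicted` — the number of people a gridded population dataset places
  inside the reservoir polygon, after two corrections described below
  (temporal matching and area-bias adjustment).

Accuracy over a set of $n$ evaluated reservoirs is summarised by two
complementary statistics:

$$\mathrm{Bias} = \frac{\sum_i P_{\mathrm{predicted},i} - \sum_i P_{\mathrm{reported},i}}{\sum_i P_{\mathrm{reported},i}} \cdot 100\% \in [-100\%, +\infty)$$

a ratio of sums that captures *systematic* over- or underestimation and is
dominated by the large reservoirs, and

$$\mathrm{sMAPE} = \frac{1}{n}\sum_{i=1}^{n} \frac{|P_{\mathrm{reported},i} - P_{\mathrm{predicted},i}|}{|P_{\mathrm{reported},i}| + |P_{\mathrm{predicted},i}|} \in [0, 1]$$

which captures per-reservoir error *variability* with every reservoir
weighted equally. The sMAPE mean runs over exactly the $n$ evaluated pairs;
a pair in which both values are zero is perfect agreement and contributes 0
(real filtered data cannot produce that case, synthetic data can). Because
bias is a ratio of sums, per-group biases recombine exactly to the global
bias when numerators and denominators are pooled — a property the test
suite checks and that stratified summaries rely on.

### Assumptions

1. Reported resettlement approximates the pre-construction population of
   the inundated footprint. Reporting error in the registers is not modelled.
2. The population map chosen for comparison represents the situation
   *before* resettlement (see temporal matching).
3. Population density in the part of the true reservoir area missed by the
   polygon equals the density inside the polygon (see area-bias adjustment).

## Pipeline stages and their parameters

### Selection filters (`filter_criteria()`, `filter_reservoirs()`)

| parameter | default | units | rationale |
|---|---|---|---|
| `min_area_km2` | 1 | km² | small reservoirs are poorly resolved by both the polygons and coarse rasters; strict `>` |
| `min_completion_year` | 1980 | year | a 5–9 year offset must still land on an available map vintage (earliest 1975); inclusive `>=` |
| `max_density_per_km2` | 1500 | persons/km² | the density threshold used to delineate cities; keeping below it keeps the sample rural; strict `<` |
| `max_area_ratio` | 5 | — | symmetric reported-vs-polygon ratio bound for the area-bias estimate; larger disagreements indicate mislinked polygons |
| `require_resettlement` | `TRUE` | — | missing counts are encoded as `NA`, never 0; a reported zero is legitimate and kept |

Whether the area and density thresholds are strict or non-strict is not
decidable from their verbal definitions ("larger than", "below"); both are
implemented strict, and the density uses reported persons over reported
area — the only density computable before any raster work. Every record is
evaluated against *every* criterion, so a rejection lists all its reasons;
filters are idempotent and partition the input.

### Temporal matching (`select_reference_year()`)

Dam completion marks the end of a gradual resettlement process that spans
the construction period (large dams take on the order of 8–9 years to
build). With map vintages every `k = 5` years, the standard rule

$$Y_{\mathrm{ref}} = Y_{\mathrm{completion}} - (k + Y_{\mathrm{completion}} \bmod k)$$

rounds the completion year down to the *second*-closest vintage, giving an
offset of 5–9 years; `mod` is the non-negative remainder. The `late` policy
subtracts one further vintage (offset 10–14 years) and exists as a
sensitivity variant. Reference years outside the configured valid range
(default 1975–2010) raise a named error at the policy level; the pipeline
logs such records as coverage gaps instead of failing the run.

### Zonal extraction (`refine_grid()`, `zonal_population()`)

Counting people "inside a polygon" from a raster needs a membership rule.
The package uses mass-preserving refinement plus centroid membership: each
native cell's count is split evenly over `refine_factor²` children (totals
are conserved exactly), and refined cells whose centroids fall inside the
polygon contribute their counts. The default `refine_factor = 10` turns
100 m cells into 10 m cells, making the discretisation error of the
boundary band small relative to multi-km² polygons while keeping cost
bounded; the factor is configurable and zonal sums converge as it grows
(tested empirically at factors 1, 2, 10).

Numerical choices: a centroid exactly on the polygon boundary counts as
inside (a consistent, measure-zero tie-break); polygons may extend beyond
the grid, with off-grid area contributing zero; the implementation
classifies whole native cells that no polygon edge can touch and enumerates
refined centroids only in a conservative band around the ring, which makes
it exactly equal to brute-force enumeration of every refined centroid — an
equality the test suite asserts against an independent scalar oracle on
over a hundred random grid/polygon instances.

### Area-bias adjustment (`estimate_mean_area_bias()`, `adjust_area_bias()`)

Reservoir polygons digitised from satellite imagery tend to capture the
water surface at whatever filling level the image happened to show, so they
under-represent the register-reported *maximum* surface area. Comparing
reported areas `A_rep` with polygon shoelace areas `A_poly` over all pairs
that pass the symmetric ratio filter gives the mean under-representation

$$b = -\frac{\sum A_{\mathrm{poly}} - \sum A_{\mathrm{rep}}}{\sum A_{\mathrm{rep}}},$$

the aggregate (ratio-of-sums) form, mirroring the bias statistic; whether
the mean should be aggregate or per-pair is genuinely open, so a per-pair
variant (`method = "per_pair"`) is provided and the aggregate form is the
default. With `b` in hand, each raw zonal count is scaled:

$$P_{\mathrm{predicted}} = \frac{P_{\mathrm{polygon}}}{1 - b}, \qquad b = 0.188 \Rightarrow \frac{1}{1-b} \approx 1.23 .$$

The default `b = 0.188` can be replaced by an estimate from the run's own
area pairs (`area_bias_source = "estimated"`). The adjustment applies the
full factor uniformly to every polygon; per-polygon adjustment would
require knowing each polygon's individual shortfall, which the data do not
provide. This inflates sMAPE slightly (polygons better represented than
average get over-corrected) while leaving the aggregate bias unbiased —
one reason bias, not sMAPE, is the headline statistic.

## The synthetic world

`synthetic_world_config()` + `generate_scenario()` build a planar world
with known truth so that every claim above is testable without external
data. What it emulates, and the defaults chosen as the package's reference
conditions:

* **Truth field**: uniform rural background (20 persons/km²) plus 25
  Gaussian settlement clusters of 20,000 persons with 1.5 km dispersion,
  on a 180 km × 180 km plane at 100 m resolution. Cluster kernels are
  integrated exactly over cells (differences of normal CDFs) and
  renormalised to their in-world mass.
* **Reservoirs**: 307 convex, pairwise-disjoint polygons with log-uniform
  areas — small reservoirs most common, a long right tail. The tail is
  truncated at 100 km² so the world and its rasters stay desk-sized; the
  real-world tail reaches thousands of km². Completion years are uniform on
  1980–2015, mapping onto every vintage 1975–2010. Placement is rejection
  sampling *anywhere* in the world: rurality is enforced by the downstream
  density filter, mirroring the pipeline's own logic rather than
  pre-censoring the sample.
* **Register table**: reported resettlement is the true zonal population of
  the *true* footprint (optionally with multiplicative lognormal noise;
  default σ = 0 so recovery checks are exact — counts are positive and
  heavy-tailed, making a lognormal the natural noise family). The reported
  area is the true polygon area.
* **Polygon shrink**: the footprints the pipeline sees are the true
  polygons scaled toward their centroids to `(1 − s)` of their area, with
  `s ~ N(0.188, 0.05)` truncated to `[0, 0.9]` — reproducing the
  reported-vs-polygon area discrepancy structure. Only the mean of the real
  shrink distribution is known, so its spread is a free parameter.
* **Derived datasets**: each synthetic "product" multiplies the truth by a
  bias factor β, smears a fraction of every cell's mass uniformly over a
  disc (edge-truncated with per-source renormalisation, so mass is
  conserved and totals scale *exactly* by β), and re-grids by block
  aggregation. The five default β values 0.47, 0.35, 0.33, 0.32, 0.16
  mirror the bias magnitudes reported for the five global population
  products in rural validation work; one dataset is fine-resolution
  (100 m) with coverage restricted to the 2000–2010 vintages, exercising
  the coverage-gap path, the others are 1 km products covering 1975–2010.

What the generator does **not** emulate: geographic (lon/lat) coordinates
and reprojection; urban morphology, roads, nightlights or building
footprints (the covariates real products use); multipolygons and holes;
register reporting errors other than multiplicative noise; any correlation
between dataset error and terrain. Passing recovery tests therefore show
that the *pipeline arithmetic* is correct and unbiased under controlled
distortions — they do not certify any real product's accuracy, which is
exactly why the synthetic biases are injected and recovered rather than
asserted.

## Numerical and I/O choices

* All geometry is planar Cartesian metres in raster (y-down) orientation;
  cell `(r, c)` has centroid `(origin_x + (c-0.5)·cs, origin_y + (r-0.5)·cs)`.
  The analysis needs only areas and containment, and a planar frame makes
  both exact and testable. Shoelace areas are orientation-independent.
* Rasters travel as ESRI ASCII grids (plain text, exact round-trip at
  15 significant digits) with `reference_year`/`dataset_name` in a JSON
  sidecar; if the sidecar is missing the caller must supply both — they are
  never guessed. Nodata cells are zero-filled on read with a logged count
  (how missing cells should be treated is not derivable from the products'
  documentation; zero is the conservative choice for count rasters).
* Polygons travel as GeoJSON FeatureCollections with an `id` property;
  coordinates are the planar metres above, not lon/lat.
* Polygon shrink scales vertices by `sqrt(1 − s)` about the area centroid:
  the area ratio is `1 − s` exactly and the centroid is unchanged.
* Convex polygons only in the generator (rejection sampling with a
  10,000-attempt cap per polygon); the extraction code itself handles any
  simple polygon.
* Degenerate inputs are named errors, not silent results: empty pair sets,
  zero reported totals, out-of-range reference years, infeasible packing,
  unknown income labels, duplicate ids.

## Problem sizes

The reference recovery experiment uses the default world: 1800×1800 truth
cells, 307 reservoirs, five derived datasets (one at 100 m, four at 1 km),
refinement factor 10 — about half a minute end to end. Unit and property
tests run on grids of tens of cells and polygons of a few vertices, where
the brute-force oracles are affordable. These sizes are the package's
reference configuration; all of them scale up through the same interfaces.

## Known limitations

* The aggregate-vs-per-pair ambiguity in the area-bias mean is resolved by
  a flag, not by evidence; the two estimators differ when the shrink is
  correlated with reservoir size.
* The uniform area-bias adjustment is unbiased in aggregate but distorts
  per-reservoir errors, inflating sMAPE.
* The centroid rule is not area-weighted overlap; for polygons comparable
  in size to a refined cell the zonal count is quantised (a polygon
  containing no refined centroid counts zero people).
* Reservoir placement ignores terrain, so the synthetic density filter
  rejects far fewer records than a real register would.
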