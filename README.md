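# popgridval

Validation of gridded population rasters against independently reported
population counts inside polygon footprints.

## The problem

Global gridded population datasets (WorldPop, GPW, GRUMP, LandScan, GHS-POP
and their kin) disaggregate census totals into raster cells using ancillary
covariates. Their calibration leans heavily on urban areas; how well they
count *rural* people is much less clear — yet rural cell counts feed
epidemiological denominators, disaster-exposure estimates and
service-planning decisions.

One of the few ground-truth sources that is fully independent of censuses is
dam-construction resettlement: when a reservoir fills, the national dam
authority reports how many people were displaced from the inundated
footprint, usually from on-the-ground surveys. Pairing those reported counts
(`P_reported`) with the population a gridded dataset places inside the
reservoir polygon gives a direct, polygon-level accuracy check in
predominantly rural settings.

`popgridval` implements that validation pipeline end to end:

1. **Selection** — inclusion filters with a full audit trail: resettlement
   data available, reported surface area > 1 km², completion year ≥ 1980,
   reported density < 1500 persons/km² (the city-delineation threshold, so
   the sample stays rural), manual exclusion flags, optional country
   exclusions.
2. **Temporal matching** — the population-map reference year representing
   the situation *before* resettlement:
   `Y_ref = Y_completion − (5 + Y_completion mod 5)`,
   i.e. the completion year rounded down to the second-closest 5-year map
   vintage (a 5–9 year offset, one typical large-dam construction period),
   with a 10–14 year "late" variant for sensitivity analysis.
3. **Extraction** — mass-preserving zonal statistics: the grid is refined
   (each cell's count split evenly over `k²` children), and all refined
   cells whose centroids fall inside the polygon are summed to `P_polygon`.
4. **Area-bias adjustment** — satellite-derived reservoir polygons
   systematically under-represent reported maximum surface areas (mean
   under-representation `b = 0.188`, estimable from the data with
   [`estimate_mean_area_bias()`] after a symmetric ratio > 5 outlier
   filter); assuming equal density in the missing rim,
   `P_predicted = P_polygon / (1 − b) ≈ 1.23 · P_polygon`.
5. **Accuracy metrics** —
   `Bias = (Σ P_predicted − Σ P_reported) / Σ P_reported · 100%`
   (ratio of sums, in [−100%, ∞)) and
   `sMAPE = mean(|P_reported − P_predicted| / (|P_reported| + |P_predicted|))`
   in [0, 1], overall and stratified by dataset, reference year, country and
   income level.

Because the real register attributes are paywalled and the real rasters are
multi-gigabyte, the package ships a **synthetic-world generator** with fully
known ground truth: a clustered population field, non-overlapping convex
reservoir polygons whose reported areas exceed their polygon areas by a
controlled shrink, register-style attribute tables, and derived gridded
datasets that are β-scaled, spatially smeared, re-gridded copies of the
truth — so the bias the pipeline should recover for a dataset is exactly
`(β − 1)·100%`, and every stage is testable without downloads.

## Worked example

```r
library(popgridval)

cfg <- synthetic_world_config(seed = 42, extent_m = 40000, n_reservoirs = 40,
                              area_range_km2 = c(1, 25))
scenario <- generate_scenario(cfg)

filtered <- filter_reservoirs(scenario$records)
kept <- dplyr::filter(filtered, kept)

pred <- predict_all(scenario$grids, scenario$polygons, kept,
                    policy = reference_year_policy("standard"),
                    b = 0.188, refine_factor = 10)
evaluate_group(pred$pairs, "dataset")
#> # A tibble: 5 × 4
#>   dataset bias_percent smape     n
#>   <chr>          <dbl> <dbl> <int>
#> 1 ds1            -51.3 0.381     9
#> 2 ds2            -64.2 0.477    40
#> 3 ds3            -66.2 0.499    40
#> 4 ds4            -67.3 0.511    40
#> 5 ds5            -83.6 0.720    40
```

The five synthetic datasets carry injected multiplicative biases
β ∈ {0.47, 0.35, 0.33, 0.32, 0.16}, i.e. true biases of −53%, −65%, −67%,
−68% and −84%; the pipeline recovers each within a few points even on this
small 40-reservoir world (`ds1` covers only the 2000–2010 vintages, hence
its smaller `n` — dams needing earlier reference years are skipped and
logged). Two one-liners behind the headline numbers:

```r
round(adjust_area_bias(100, 0.188), 2)  # 123.15 — the 1.23x adjustment
select_reference_year(2008)             # 2000 — vintage for a 2008 dam
```

File-based runs use `run_config()` + `run_validation()` (which writes pairs,
stratified metrics, audit logs and a run log), `run_report()` re-analyses a
pairs CSV without rasters, and `inst/cli/popgridval` exposes
`simulate` / `validate` / `report` subcommands for shell use. Results have
`tidy()`, `glance()` and `autoplot()` methods.

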