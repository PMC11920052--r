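test_that("background-only field is uniform with the exact total", {
  cfg <- synthetic_world_config(seed = 1, extent_m = 10000,
                                true_cell_size_m = 100, n_clusters = 0,
                                background_density_per_km2 = 10,
                                n_reservoirs = 0, area_range_km2 = c(1, 4),
                                dataset_specs = default_dataset_specs()[0, ])
  g <- generate_true_field(cfg)
  expect_true(all(abs(g$counts - 0.1) < 1e-12)) # 10 /km2 on 0.01 km2 cells
  expect_equal(grid_total(g), 1000)
})

test_that("generators are deterministic given the seed", {
  cfg <- small_world_config(seed = 5)
  g1 <- generate_true_field(cfg)
  g2 <- generate_true_field(cfg)
  expect_identical(g1$counts, g2$counts)
  r1 <- sample_reservoirs(cfg, g1)
  r2 <- sample_reservoirs(cfg, g2)
  expect_identical(r1$ring, r2$ring)
  expect_identical(r1$completion_year, r2$completion_year)
})

test_that("cluster mass averages to the configured intensity over seeds", {
  totals <- vapply(1:20, function(s) {
    cfg <- synthetic_world_config(seed = s, extent_m = 20000,
                                  true_cell_size_m = 200, n_clusters = 5,
                                  cluster_intensity = 1000,
                                  cluster_spread_m = 500,
                                  background_density_per_km2 = 0,
                                  n_reservoirs = 0,
                                  dataset_specs = default_dataset_specs()[0, ])
    grid_total(generate_true_field(cfg))
  }, numeric(1))
  expect_equal(mean(totals), 5000, tolerance = 0.05)
})

test_that("sampled reservoirs respect areas, years, extent and disjointness", {
  cfg <- small_world_config(seed = 6)
  field <- generate_true_field(cfg)
  res <- sample_reservoirs(cfg, field)
  expect_identical(nrow(res), 12L)
  expect_true(all(res$area_km2 >= 1 & res$area_km2 <= 8))
  expect_true(all(res$completion_year >= 1980 & res$completion_year <= 2015))
  for (rg in res$ring) {
    expect_true(all(rg >= 0 & rg <= 20000))
  }
  # pairwise disjoint: no Monte-Carlo point falls inside two polygons
  set.seed(99)
  px <- runif(20000, 0, 20000); py <- runif(20000, 0, 20000)
  hits <- rowSums(vapply(res$ring,
                         function(rg) point_in_polygon(px, py, rg),
                         logical(length(px))))
  expect_true(all(hits <= 1))
})

test_that("a degenerate area range produces the requested area", {
  cfg <- synthetic_world_config(seed = 2, extent_m = 10000,
                                true_cell_size_m = 100, n_reservoirs = 1,
                                area_range_km2 = c(4, 4),
                                dataset_specs = default_dataset_specs()[0, ])
  res <- sample_reservoirs(cfg, generate_true_field(cfg))
  expect_equal(res$area_km2, 4, tolerance = 0.01)
})

test_that("infeasible packing raises a named error", {
  cfg <- synthetic_world_config(seed = 3, extent_m = 10000,
                                true_cell_size_m = 100, n_reservoirs = 50,
                                area_range_km2 = c(2, 20),
                                dataset_specs = default_dataset_specs()[0, ])
  expect_error(sample_reservoirs(cfg, generate_true_field(cfg)),
               "infeasible packing|could not place")
})

test_that("derived datasets scale totals by beta and conserve reallocated mass", {
  cfg <- small_world_config(seed = 7)
  field <- generate_true_field(cfg)
  spec_id <- list(dataset = "id", beta = 1, realloc_fraction = 0,
                  realloc_radius_m = 0, out_cell_size_m = 100)
  expect_identical(derive_gridded_dataset(field, spec_id)$counts, field$counts)

  spec_half <- list(dataset = "half", beta = 0.5, realloc_fraction = 0,
                    realloc_radius_m = 0, out_cell_size_m = 100)
  expect_equal(grid_total(derive_gridded_dataset(field, spec_half)),
               0.5 * grid_total(field), tolerance = 1e-9)

  spec_mix <- list(dataset = "mix", beta = 0.47, realloc_fraction = 0.3,
                   realloc_radius_m = 500, out_cell_size_m = 1000)
  d <- derive_gridded_dataset(field, spec_mix)
  expect_equal(grid_total(d), 0.47 * grid_total(field),
               tolerance = 1e-6)
  expect_equal(d$cell_size, 1000)

  # linearity in beta on randomized fields
  set.seed(71)
  for (k in 1:5) {
    beta <- runif(1, 0.1, 2)
    spec <- list(dataset = "x", beta = beta,
                 realloc_fraction = runif(1),
                 realloc_radius_m = sample(c(0, 200, 400), 1),
                 out_cell_size_m = sample(c(100, 500, 1000), 1))
    expect_equal(grid_total(derive_gridded_dataset(field, spec)),
                 beta * grid_total(field), tolerance = 1e-6)
  }
})

test_that("noiseless reports equal true zonal counts; lognormal noise centres on 1", {
  cfg <- small_world_config(seed = 8)
  field <- generate_true_field(cfg)
  res <- sample_reservoirs(cfg, field)
  tab0 <- generate_icold_table(field, res, cfg, refine_factor = 4)
  truth <- vapply(res$ring, function(rg) zonal_population(field, rg, 4),
                  numeric(1))
  expect_equal(tab0$resettled_persons, truth, tolerance = 1e-12)
  expect_equal(tab0$reported_area_km2, res$area_km2)
  expect_false(any(tab0$excluded_transboundary | tab0$excluded_preexisting))

  # an empty region reports zero people
  empty_cfg <- synthetic_world_config(seed = 9, extent_m = 10000,
                                      true_cell_size_m = 100,
                                      background_density_per_km2 = 0,
                                      n_clusters = 0, n_reservoirs = 1,
                                      area_range_km2 = c(2, 2),
                                      dataset_specs = default_dataset_specs()[0, ])
  ef <- generate_true_field(empty_cfg)
  er <- sample_reservoirs(empty_cfg, ef)
  expect_equal(generate_icold_table(ef, er, empty_cfg)$resettled_persons, 0)

  # multiplicative noise: mean log ratio near 0 over many reservoirs
  noisy_cfg <- synthetic_world_config(
    seed = 10, extent_m = 60000, true_cell_size_m = 200,
    n_clusters = 0, background_density_per_km2 = 25,
    n_reservoirs = 200, area_range_km2 = c(0.5, 2),
    report_noise_sd = 0.2,
    dataset_specs = default_dataset_specs()[0, ])
  nf <- generate_true_field(noisy_cfg)
  nr <- sample_reservoirs(noisy_cfg, nf)
  noisy <- generate_icold_table(nf, nr, noisy_cfg, refine_factor = 2)
  clean_cfg <- noisy_cfg
  clean_cfg$report_noise_sd <- 0
  clean <- generate_icold_table(nf, nr, clean_cfg, refine_factor = 2)
  expect_lt(abs(mean(log(noisy$resettled_persons / clean$resettled_persons))),
            0.05)
})

test_that("generate_scenario wires files and manifest through the I/O layer", {
  dir <- withr::local_tempdir()
  cfg <- small_world_config(seed = 12)
  sc <- generate_scenario(cfg, dir)
  expect_true(file.exists(file.path(dir, "truth.asc")))
  expect_true(file.exists(file.path(dir, "polygons.geojson")))
  expect_true(file.exists(file.path(dir, "records.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # every (dataset, vintage) raster written and readable
  expect_true(all(file.exists(file.path(dir, sprintf(
    "%s_%d.asc", sc$grids$dataset, sc$grids$reference_year)))))
  g <- read_population_raster(file.path(dir, "fine_2000.asc"))
  expect_identical(g$dataset_name, "fine")
  expect_identical(g$reference_year, 2000L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$datasets$fine, 1)
  expect_equal(man$datasets$coarse, 0.5)
  # the shrunken polygons the pipeline sees under-represent reported areas
  expect_true(all(sc$polygons$area_km2 < sc$records$reported_area_km2))
})
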