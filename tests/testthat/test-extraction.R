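test_that("zonal sum is exact on an axis-aligned cover and empty on a sliver", {
  g <- pop_grid(matrix(1, 20, 20), 100)
  # square strictly containing the 5x5 block of centroids (250..650 m)
  sq <- cbind(c(240, 740, 740, 240), c(240, 240, 740, 740))
  expect_equal(zonal_population(g, sq, 1), 25)
  # polygon between refined centroids: contains none, sums to zero
  sliver <- cbind(c(106, 109, 109, 106), c(106, 106, 109, 109))
  expect_equal(zonal_population(g, sliver, 10), 0)
  expect_error(zonal_population(g, sq, 0), "positive integer")
})

test_that("zonal extraction matches the exhaustive enumeration oracle", {
  set.seed(51)
  for (k in 1:12) {
    nr <- sample(8:14, 1)
    g <- pop_grid(matrix(rexp(nr * nr, 1 / 5), nr, nr), 100,
                  origin_x = runif(1, -500, 500), origin_y = runif(1, -500, 500))
    extent <- nr * 100
    ring <- random_test_ring(g$origin_x + runif(1, 0, extent),
                             g$origin_y + runif(1, 0, extent),
                             runif(1, 150, extent / 2))
    for (r in c(1L, 2L, 10L)) {
      expect_equal(zonal_population(g, ring, r), oracle_zonal(g, ring, r),
                   tolerance = 1e-12)
    }
  }
})

test_that("zonal sums are additive over disjoint polygons and bounded", {
  g <- pop_grid(matrix(runif(400, 0, 3), 20, 20), 100)
  a <- cbind(c(100, 800, 800, 100), c(100, 100, 800, 800))
  b <- cbind(c(1200, 1900, 1900, 1200), c(1200, 1200, 1900, 1900))
  za <- zonal_population(g, a, 5)
  zb <- zonal_population(g, b, 5)
  expect_lte(za + zb, grid_total(g))
  expect_gt(za, 0)
  # partial overlap with the grid: outside cells contribute 0
  off <- cbind(c(-1000, 500, 500, -1000), c(-1000, -1000, 500, 500))
  expect_lte(zonal_population(g, off, 5), grid_total(g))
})

test_that("zonal sums converge as the refinement factor grows", {
  set.seed(52)
  err <- function(r, g, ring, zref) abs(zonal_population(g, ring, r) - zref)
  e1 <- e10 <- 0
  for (k in 1:5) {
    g <- pop_grid(matrix(runif(144, 0, 5), 12, 12), 100)
    ring <- random_test_ring(600, 600, 450)
    zref <- zonal_population(g, ring, 50L)
    e1 <- e1 + err(1L, g, ring, zref)
    e10 <- e10 + err(10L, g, ring, zref)
  }
  expect_lt(e10, e1)
})

test_that("area-bias adjustment is the 1/(1-b) scaling", {
  expect_equal(adjust_area_bias(100, 0.188), 100 / 0.812)
  expect_equal(round(adjust_area_bias(1, 0.188), 2), 1.23)
  expect_equal(adjust_area_bias(7, 0), 7)
  expect_equal(adjust_area_bias(7, 0.5), 14)
  # linear and order-preserving
  expect_equal(adjust_area_bias(c(1, 2, 5), 0.3), c(1, 2, 5) / 0.7)
  expect_error(adjust_area_bias(-1, 0.2), ">= 0")
  expect_error(adjust_area_bias(1, 1), "b < 1")
})

test_that("mean area bias is estimated from filtered pairs", {
  set.seed(53)
  ring_of_area <- function(a_km2) {
    side <- sqrt(a_km2) * 1000
    cbind(c(0, side, side, 0), c(0, 0, side, side))
  }
  polys <- reservoir_polygons(c("a", "b"),
                              list(ring_of_area(81.2), ring_of_area(100)))
  recs <- dplyr::bind_rows(make_record("a", area = 100),
                           make_record("b", area = 600)) # ratio 6: outlier
  est <- estimate_mean_area_bias(recs, polys)
  expect_equal(est$b, 0.188, tolerance = 1e-9)
  expect_identical(est$n_pairs_used, 1L)
  expect_identical(est$n_outliers_removed, 1L)
  expect_equal(adjust_area_bias(100, est), 100 / 0.812)

  # all pairs equal -> b = 0, both estimators
  polys2 <- reservoir_polygons(c("a", "b"),
                               list(ring_of_area(10), ring_of_area(20)))
  recs2 <- dplyr::bind_rows(make_record("a", area = 10),
                            make_record("b", area = 20))
  expect_equal(estimate_mean_area_bias(recs2, polys2)$b, 0, tolerance = 1e-9)
  expect_equal(estimate_mean_area_bias(recs2, polys2,
                                       method = "per_pair")$b, 0,
               tolerance = 1e-9)
})

test_that("predict_all pairs every kept record with every covered dataset", {
  g1 <- pop_grid(matrix(2, 10, 10), 100, reference_year = 1985L,
                 dataset_name = "dsA")
  g2 <- pop_grid(matrix(4, 10, 10), 100, reference_year = 1985L,
                 dataset_name = "dsB")
  g3 <- pop_grid(matrix(4, 10, 10), 100, reference_year = 2000L,
                 dataset_name = "dsB")
  grids <- tibble::tibble(dataset = c("dsA", "dsB", "dsB"),
                          reference_year = c(1985L, 1985L, 2000L),
                          grid = list(g1, g2, g3))
  ring <- cbind(c(140, 660, 660, 140), c(140, 140, 660, 660))
  polys <- reservoir_polygons(c("a", "b"), list(ring, ring + 200))
  recs <- dplyr::bind_rows(make_record("a", year = 1992),  # ref 1985
                           make_record("b", year = 1992))
  out <- predict_all(grids, polys, recs, b = 0)
  expect_identical(nrow(out$pairs), 4L)
  expect_identical(nrow(out$skipped), 0L)
  expect_equal(out$pairs$p_predicted, out$pairs$p_polygon)

  # a record whose reference year only dsB covers is skipped for dsA
  recs2 <- dplyr::bind_rows(recs, make_record("a2", year = 2008))
  polys2 <- dplyr::bind_rows(polys, reservoir_polygons("a2", ring + 100))
  out2 <- predict_all(grids, polys2, recs2, b = 0)
  expect_identical(nrow(out2$pairs), 5L)
  expect_identical(out2$skipped$dataset, "dsA")
  expect_match(out2$skipped$reason, "no dsA grid for reference year 2000")
})
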