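pairs_tbl <- function(reported, predicted, ...) {
  tibble::tibble(p_reported = reported, p_predicted = predicted, ...)
}

test_that("bias percentage matches hand-computed cases and bounds", {
  expect_equal(bias_percentage(pairs_tbl(c(10, 100, 1000), c(10, 100, 1000))), 0)
  expect_equal(bias_percentage(pairs_tbl(c(100, 300), c(50, 150))), -50)
  expect_equal(bias_percentage(pairs_tbl(c(10, 90), c(0, 0))), -100)
  expect_error(bias_percentage(pairs_tbl(c(0, 0), c(1, 2))), "undefined")
  # order invariance and the -100 lower bound on random pairs
  set.seed(61)
  for (k in 1:10) {
    rep_v <- runif(20, 1, 1000)
    pred_v <- runif(20, 0, 1500)
    p <- pairs_tbl(rep_v, pred_v)
    expect_gte(bias_percentage(p), -100)
    shuf <- p[sample(20), ]
    expect_equal(bias_percentage(shuf), bias_percentage(p))
  }
})

test_that("sMAPE matches hand-computed cases, stays in [0,1], is symmetric", {
  expect_equal(smape(pairs_tbl(100, 100)), 0)
  expect_equal(smape(pairs_tbl(c(10, 100, 1000), c(0, 0, 0))), 1)
  expect_equal(smape(pairs_tbl(100, 50)), 1 / 3)
  expect_equal(smape(pairs_tbl(c(0, 100), c(0, 100))), 0) # 0/0 pair contributes 0
  set.seed(62)
  for (k in 1:10) {
    a <- runif(15, 0, 100); b <- runif(15, 0, 100)
    s <- smape(pairs_tbl(a, b))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(smape(pairs_tbl(b, a)), s) # reported/predicted swap
    # uniform positive rescaling of one pair leaves its term unchanged
    a2 <- a; b2 <- b; a2[1] <- 7 * a[1]; b2[1] <- 7 * b[1]
    expect_equal(smape(pairs_tbl(a2, b2)), s)
  }
})

test_that("group-wise biases pool exactly to the global bias", {
  set.seed(63)
  for (k in 1:10) {
    n <- 30
    pairs <- pairs_tbl(runif(n, 1, 500), runif(n, 0, 700),
                       dataset = "d",
                       reference_year = sample(c(1990L, 2000L, 2010L), n, TRUE),
                       country = sample(c("BRA", "CHN", "IND"), n, TRUE),
                       income_level = "low")
    by_year <- evaluate_group(pairs, "reference_year")
    # ratio of sums: recombine numerators and denominators per group
    reported <- vapply(by_year$reference_year, function(y)
      sum(pairs$p_reported[pairs$reference_year == y]), numeric(1))
    pooled <- sum(by_year$bias_percent / 100 * reported) / sum(reported) * 100
    expect_equal(pooled, bias_percentage(pairs), tolerance = 1e-9)
  }
})

test_that("grouping by a single-level key reproduces ungrouped metrics", {
  pairs <- pairs_tbl(c(10, 20), c(5, 30), dataset = "only")
  g <- evaluate_group(pairs, "dataset")
  expect_identical(nrow(g), 1L)
  expect_equal(g$bias_percent, bias_percentage(pairs))
  expect_equal(g$smape, smape(pairs))
})

test_that("year-range restriction drops out-of-range pairs before grouping", {
  pairs <- pairs_tbl(rep(100, 6), rep(50, 6),
                     dataset = "d",
                     reference_year = c(1975L, 1990L, 2000L, 2005L, 2010L, 1985L),
                     income_level = rep(c("low", "high"), 3))
  out <- evaluate_group(pairs, "income_level", year_range = c(2000, 2010))
  expect_equal(sum(out$n), 3L)
  expect_error(evaluate_group(pairs, "income_level", year_range = c(2020, 2030)),
               "no pairs")
  expect_error(evaluate_group(pairs, "not_a_key"), "unknown group key")
})

test_that("country means average available datasets only", {
  res <- tibble::tibble(
    dataset = c("d1", "d2", "d1", "d1", "d2", "d3", "d4", "d5"),
    country = c("BRA", "BRA", "CHN", rep("IND", 5)),
    bias_percent = c(-50, -70, -42, -10, -20, -30, -40, -100),
    smape = 0.5, n = 3L
  )
  out <- country_mean_bias(res)
  expect_equal(out$mean_bias_percent[out$country == "BRA"], -60)
  expect_equal(out$mean_bias_percent[out$country == "CHN"], -42) # single dataset
  expect_equal(out$mean_bias_percent[out$country == "IND"], -40) # 5 of 5
  expect_identical(out$n_datasets[out$country == "BRA"], 2L)
})

test_that("diagnostic plots return ggplot objects", {
  pairs <- pairs_tbl(c(10, 100, 0), c(5, 120, 4), dataset = "d",
                     reference_year = c(1990L, 2000L, 2010L))
  expect_message(p <- plot_validation_scatter(pairs), "dropping 1")
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_group_bias(evaluate_group(pairs, "dataset")), "ggplot")
})
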