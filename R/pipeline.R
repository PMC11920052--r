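#' Configuration for a validation run
#'
#' Bundles every per-stage parameter: input paths, inclusion criteria,
#' reference-year policy, the refinement factor of the centroid zonal rule,
#' and how the polygon area under-representation `b` is obtained — either a
#' fixed value (default 0.188) or estimated from the run's own
#' reported-vs-polygon area pairs.
#'
#' @param rasters_dir Directory of `<dataset>_<year>.asc` rasters (with
#'   metadata sidecars).
#' @param polygons_path GeoJSON file of reservoir footprints.
#' @param records_path CSV attribute table.
#' @param output_dir Directory for all run outputs (created if missing).
#' @param criteria A [filter_criteria()].
#' @param policy A [reference_year_policy()].
#' @param refine_factor Centroid-rule refinement (default 10).
#' @param area_bias_source `"fixed"` or `"estimated"`.
#' @param fixed_b Under-representation fraction used when
#'   `area_bias_source = "fixed"` (default 0.188).
#' @param year_range Optional `c(min, max)` restriction on reference years
#'   in the income-level summary.
#' @param seed Integer seed echoed into the run log (the validation itself
#'   is deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(rasters_dir, polygons_path, records_path,
                       output_dir = NULL,
                       criteria = filter_criteria(),
                       policy = reference_year_policy(),
                       refine_factor = 10L,
                       area_bias_source = c("fixed", "estimated"),
                       fixed_b = 0.188,
                       year_range = NULL,
                       seed = 1L) {
  area_bias_source <- match.arg(area_bias_source)
  stopifnot(fixed_b < 1)
  structure(
    list(rasters_dir = rasters_dir, polygons_path = polygons_path,
         records_path = records_path, output_dir = output_dir,
         criteria = criteria, policy = policy,
         refine_factor = as.integer(refine_factor),
         area_bias_source = area_bias_source, fixed_b = fixed_b,
         year_range = year_range, seed = as.integer(seed)),
    class = "run_config"
  )
}

read_raster_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  files <- files[basename(files) != "truth.asc"]
  if (!length(files)) stop(sprintf("no .asc rasters in %s", dir), call. = FALSE)
  rows <- lapply(files, function(f) {
    g <- read_population_raster(f)
    tibble::tibble(dataset = g$dataset_name,
                   reference_year = g$reference_year,
                   grid = list(g))
  })
  dplyr::bind_rows(rows)
}

#' Run the full validation pipeline
#'
#' Reads rasters, polygons and attribute records; applies the inclusion
#' filters; resolves each dam's map reference year; extracts and adjusts
#' polygon populations for every dataset; and computes overall and
#' stratified accuracy metrics. Everything dropped along the way (filter
#' rejection, temporal coverage gap, unmatched id) lands in exactly one
#' audit table with a reason. With `output_dir` set, writes `pairs.csv`,
#' `metrics_*.csv`, `summary.json`, `audit_*.csv` and `run_log.txt`.
#'
#' @param config A [run_config()].
#' @return A `popgrid_validation` object: list with `pairs`, `metrics`
#'   (per-dataset), `by_year`, `by_income`, `by_country`, `country_means`,
#'   `b` (the adjustment used), `audits`, `config`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  grids <- read_raster_dir(config$rasters_dir)
  polygons <- read_reservoir_polygons(config$polygons_path)
  records <- read_reservoir_table(config$records_path)

  matched <- match_records_polygons(records, polygons)
  flt <- filter_reservoirs(records, config$criteria)
  kept <- flt[flt$kept & flt$id %in% polygons$id, ]

  b_est <- NULL
  if (config$area_bias_source == "estimated") {
    b_est <- estimate_mean_area_bias(records, polygons,
                                     max_ratio = config$criteria$max_area_ratio)
    b <- b_est$b
  } else {
    b <- config$fixed_b
  }

  pred <- predict_all(grids, polygons, kept, config$policy, b,
                      config$refine_factor)
  pairs <- pred$pairs
  if (!nrow(pairs)) stop("no validation pairs produced", call. = FALSE)

  result <- structure(
    list(
      pairs = pairs,
      metrics = evaluate_group(pairs, "dataset"),
      by_year = evaluate_group(pairs, c("dataset", "reference_year")),
      by_income = evaluate_group(pairs, c("dataset", "income_level"),
                                 year_range = config$year_range),
      by_country = evaluate_group(pairs, c("dataset", "country")),
      b = b,
      b_estimate = b_est,
      audits = list(
        unmatched = matched$audit,
        filter = dplyr::select(flt, "id", "kept", "reasons"),
        coverage = pred$skipped
      ),
      config = config
    ),
    class = "popgrid_validation"
  )
  result$country_means <- country_mean_bias(result$by_country)

  if (!is.null(config$output_dir)) write_validation_outputs(result)
  result
}

write_validation_outputs <- function(result) {
  config <- result$config
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$pairs, file.path(out, "pairs.csv"), progress = FALSE)
  readr::write_csv(result$metrics, file.path(out, "metrics_by_dataset.csv"),
                   progress = FALSE)
  readr::write_csv(result$by_year, file.path(out, "metrics_by_year.csv"),
                   progress = FALSE)
  readr::write_csv(result$by_income, file.path(out, "metrics_by_income.csv"),
                   progress = FALSE)
  readr::write_csv(result$by_country, file.path(out, "metrics_by_country.csv"),
                   progress = FALSE)
  readr::write_csv(result$country_means, file.path(out, "country_mean_bias.csv"),
                   progress = FALSE)
  readr::write_csv(result$audits$filter, file.path(out, "audit_filter.csv"),
                   progress = FALSE)
  readr::write_csv(result$audits$coverage, file.path(out, "audit_coverage.csv"),
                   progress = FALSE)
  readr::write_csv(result$audits$unmatched, file.path(out, "audit_unmatched.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(
      b = result$b,
      adjustment_factor = 1 / (1 - result$b),
      n_pairs = nrow(result$pairs),
      datasets = purrr::transpose(as.list(result$metrics))
    ),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    "popgrid validation run",
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("package version: %s",
            as.character(utils::packageVersion("popgridval"))),
    sprintf("seed: %d", config$seed),
    sprintf("refine_factor: %d", config$refine_factor),
    sprintf("area_bias_source: %s (b = %.4f)", config$area_bias_source, result$b),
    sprintf("criteria: min_area %g km2, min_year %d, max_density %g /km2, max_ratio %g",
            config$criteria$min_area_km2, config$criteria$min_completion_year,
            config$criteria$max_density_per_km2, config$criteria$max_area_ratio),
    sprintf("excluded countries: %s",
            if (length(config$criteria$exclude_countries))
              paste(config$criteria$exclude_countries, collapse = ", ")
            else "none"),
    sprintf("policy: %s, vintages every %d years, valid %d-%d",
            config$policy$mode, config$policy$interval_years,
            config$policy$valid_reference_years[1],
            config$policy$valid_reference_years[2])
  ), file.path(out, "run_log.txt"))
  invisible(out)
}

#' @export
print.popgrid_validation <- function(x, ...) {
  cat(sprintf("<popgrid_validation> %d pairs, %d dataset(s), b = %.4f\n",
              nrow(x$pairs), nrow(x$metrics), x$b))
  print(x$metrics)
  invisible(x)
}

#' @rdname run_validation
#' @param x A `popgrid_validation` object.
#' @param ... Unused.
#' @export
tidy.popgrid_validation <- function(x, ...) {
  x$metrics
}

#' @rdname run_validation
#' @export
glance.popgrid_validation <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_reservoirs = dplyr::n_distinct(x$pairs$id),
    n_datasets = nrow(x$metrics),
    b = x$b,
    adjustment_factor = 1 / (1 - x$b),
    n_filtered_out = sum(!x$audits$filter$kept),
    n_coverage_gaps = nrow(x$audits$coverage)
  )
}

#' @rdname run_validation
#' @param object A `popgrid_validation` object.
#' @export
autoplot.popgrid_validation <- function(object, ...) {
  plot_validation_scatter(object$pairs)
}

#' Generate a synthetic scenario to disk
#'
#' Thin orchestration wrapper over [generate_scenario()].
#'
#' @param config A [synthetic_world_config()].
#' @param dir Output directory.
#' @return The scenario bundle, invisibly.
#' @export
run_simulate <- function(config, dir) {
  invisible(generate_scenario(config, dir))
}

#' Recompute accuracy summaries from a pairs table
#'
#' Re-analysis entry point: takes a pairs CSV (as written by
#' [run_validation()]) or an in-memory pairs tibble and recomputes every
#' summary without touching rasters.
#'
#' @param pairs Path to a pairs CSV, or a pairs tibble.
#' @param exclude_countries Optional ISO3 codes to drop before summarising.
#' @param year_range Optional `c(min, max)` restriction on reference years
#'   for the income-level summary.
#' @param output_dir Optional directory for summary CSVs.
#' @return A `popgrid_report`: list with `pairs`, `metrics`, `by_year`,
#'   `by_income`, `by_country`, `country_means`.
#' @export
run_report <- function(pairs, exclude_countries = character(),
                       year_range = NULL, output_dir = NULL) {
  if (is.character(pairs)) {
    pairs <- readr::read_csv(pairs, show_col_types = FALSE, progress = FALSE)
  }
  pairs <- tibble::as_tibble(pairs)
  if (!nrow(pairs)) stop("no pairs: the pairs table is empty", call. = FALSE)
  check_pairs(pairs)
  if (length(exclude_countries)) {
    pairs <- dplyr::filter(pairs, !.data$country %in% exclude_countries)
    if (!nrow(pairs)) stop("no pairs left after country exclusion", call. = FALSE)
  }
  out <- list(
    pairs = pairs,
    metrics = evaluate_group(pairs, "dataset"),
    by_year = evaluate_group(pairs, c("dataset", "reference_year")),
    by_income = evaluate_group(pairs, c("dataset", "income_level"),
                               year_range = year_range),
    by_country = evaluate_group(pairs, c("dataset", "country"))
  )
  out$country_means <- country_mean_bias(out$by_country)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out$metrics, file.path(output_dir, "metrics_by_dataset.csv"),
                     progress = FALSE)
    readr::write_csv(out$by_year, file.path(output_dir, "metrics_by_year.csv"),
                     progress = FALSE)
    readr::write_csv(out$by_income, file.path(output_dir, "metrics_by_income.csv"),
                     progress = FALSE)
    readr::write_csv(out$by_country, file.path(output_dir, "metrics_by_country.csv"),
                     progress = FALSE)
    readr::write_csv(out$country_means,
                     file.path(output_dir, "country_mean_bias.csv"),
                     progress = FALSE)
  }
  structure(out, class = "popgrid_report")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
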