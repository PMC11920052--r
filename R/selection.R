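#' Reservoir inclusion criteria
#'
#' The filters that carve the validation sample out of the raw register:
#' resettlement data must be available, the reported surface area must exceed
#' 1 km² (too-small reservoirs are poorly resolved by the polygons), the dam
#' must have been completed in 1980 or later (so a 5–9 year offset still
#' lands on an available map vintage), and the reported population density in
#' the reservoir area must stay below 1500 persons/km² — the density
#' threshold used to delineate cities, so the filter keeps the sample rural.
#' Manually flagged transboundary dams and dam reconstructions are excluded,
#' as is any country on the `exclude_countries` list (used for
#' leave-one-country-out sensitivity runs).
#'
#' Both numeric thresholds are strict inequalities.
#'
#' @param min_area_km2 Reported-area threshold in km² (default 1).
#' @param min_completion_year Earliest admissible completion year (default
#'   1980; this bound is inclusive).
#' @param max_density_per_km2 Rurality ceiling in persons/km² (default 1500),
#'   applied to `resettled_persons / reported_area_km2` — the only density
#'   computable before any raster work.
#' @param max_area_ratio Symmetric reported-vs-polygon area ratio bound used
#'   by [area_outlier_filter()] (default 5).
#' @param require_resettlement Drop records with missing resettlement counts
#'   (default `TRUE`). A reported zero is kept.
#' @param exclude_countries Character vector of ISO3 codes to drop.
#' @return A `filter_criteria` object.
#' @export
filter_criteria <- function(min_area_km2 = 1,
                            min_completion_year = 1980L,
                            max_density_per_km2 = 1500,
                            max_area_ratio = 5,
                            require_resettlement = TRUE,
                            exclude_countries = character()) {
  stopifnot(min_area_km2 > 0, min_completion_year > 0,
            max_density_per_km2 > 0, max_area_ratio > 0)
  structure(
    list(min_area_km2 = min_area_km2,
         min_completion_year = as.integer(min_completion_year),
         max_density_per_km2 = max_density_per_km2,
         max_area_ratio = max_area_ratio,
         require_resettlement = isTRUE(require_resettlement),
         exclude_countries = as.character(exclude_countries)),
    class = "filter_criteria"
  )
}

#' Apply the reservoir inclusion filters, with an audit trail
#'
#' Evaluates every criterion on every record (no short-circuiting), so each
#' rejected record carries the complete list of violated criteria. Filtering
#' is idempotent and order-independent: kept and rejected records partition
#' the input.
#'
#' @param records Validated record tibble ([read_reservoir_table()]).
#' @param criteria A [filter_criteria()].
#' @return The input tibble with two added columns: `kept` (logical) and
#'   `reasons` (semicolon-joined violation descriptions, `""` when kept).
#' @examples
#' recs <- tibble::tibble(
#'   id = "a", country = "BRA", income_level = factor("low", c("low",
#'     "lower-middle", "upper-middle", "high")), completion_year = 1990L,
#'   reported_area_km2 = 4, resettled_persons = 400,
#'   excluded_transboundary = FALSE, excluded_preexisting = FALSE)
#' filter_reservoirs(recs)$kept
#' @export
filter_reservoirs <- function(records, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  records <- validate_records(records)
  n <- nrow(records)
  if (n == 0) {
    return(dplyr::mutate(records, kept = logical(0), reasons = character(0)))
  }
  density <- records$resettled_persons / records$reported_area_km2

  checks <- list(
    `resettlement data missing` =
      if (criteria$require_resettlement) is.na(records$resettled_persons)
      else rep(FALSE, n),
    area = records$reported_area_km2 <= criteria$min_area_km2,
    year = records$completion_year < criteria$min_completion_year,
    density = !is.na(density) & density >= criteria$max_density_per_km2,
    `flagged transboundary` = records$excluded_transboundary %in% TRUE,
    `flagged pre-existing reservoir` = records$excluded_preexisting %in% TRUE,
    `country excluded` = records$country %in% criteria$exclude_countries
  )
  msgs <- list(
    area = sprintf("area %g km2 <= %g km2", records$reported_area_km2,
                   criteria$min_area_km2),
    year = sprintf("completion year %d < %d", records$completion_year,
                   criteria$min_completion_year),
    density = sprintf("density %g >= %g persons/km2", round(density, 3),
                      criteria$max_density_per_km2),
    `country excluded` = sprintf("country %s excluded", records$country)
  )
  reason_mat <- vapply(names(checks), function(nm) {
    out <- character(n)
    hit <- checks[[nm]]
    out[hit] <- if (nm %in% names(msgs)) msgs[[nm]][hit] else nm
    out
  }, character(n))
  if (n == 1) reason_mat <- matrix(reason_mat, nrow = 1,
                                   dimnames = list(NULL, names(checks)))
  reasons <- apply(reason_mat, 1, function(r) paste(r[nzchar(r)], collapse = "; "))
  dplyr::mutate(records, kept = !nzchar(reasons), reasons = reasons)
}

#' Filter area pairs for the area-bias estimate
#'
#' Keeps reservoirs whose reported and polygon-derived surface areas are
#' mutually consistent: the symmetric ratio
#' `max(reported / polygon, polygon / reported)` must not exceed `max_ratio`
#' (unrealistically large disagreements usually indicate a mislinked polygon,
#' not a partially filled reservoir), and the reported area must exceed
#' 1 km².
#'
#' @param pairs Tibble with columns `reported_area_km2` and
#'   `polygon_area_km2`, both positive.
#' @param max_ratio Symmetric ratio bound (default 5).
#' @param min_area_km2 Reported-area floor in km² (default 1, strict).
#' @return The input tibble with added `kept` (logical) and `drop_reason`
#'   columns.
#' @export
area_outlier_filter <- function(pairs, max_ratio = 5, min_area_km2 = 1) {
  stopifnot(all(c("reported_area_km2", "polygon_area_km2") %in% names(pairs)))
  if (any(pairs$reported_area_km2 <= 0 | pairs$polygon_area_km2 <= 0)) {
    stop("all areas must be > 0", call. = FALSE)
  }
  ratio <- pmax(pairs$reported_area_km2 / pairs$polygon_area_km2,
                pairs$polygon_area_km2 / pairs$reported_area_km2)
  small <- pairs$reported_area_km2 <= min_area_km2
  outlier <- ratio > max_ratio
  dplyr::mutate(
    tibble::as_tibble(pairs),
    kept = !small & !outlier,
    drop_reason = dplyr::case_when(
      small ~ sprintf("reported area <= %g km2", min_area_km2),
      outlier ~ sprintf("area ratio %.3g > %g", ratio, max_ratio),
      TRUE ~ ""
    )
  )
}
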