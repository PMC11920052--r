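#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

INCOME_LEVELS <- c("low", "lower-middle", "upper-middle", "high")

#' Read a reservoir attribute table
#'
#' The attribute table is the register-style companion of the polygon file:
#' one row per reservoir with the reported resettlement count, the reported
#' maximum surface area, the dam completion year, country and income-level
#' classification, and two manual exclusion flags (transboundary dams and
#' dams replacing a pre-existing reservoir).
#'
#' Missing resettlement counts are encoded as empty cells / `NA`, never as 0:
#' a reported zero is a legitimate observation and is kept.
#'
#' @param path CSV file with a header naming every field of the record:
#'   `id`, `country`, `income_level`, `completion_year`, `reported_area_km2`,
#'   `resettled_persons`, `excluded_transboundary`, `excluded_preexisting`.
#' @return A tibble with one row per record, `income_level` as a factor with
#'   levels low < lower-middle < upper-middle < high.
#' @export
read_reservoir_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("attribute table not found: %s", path), call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_records(df)
}

#' Validate a reservoir record table
#'
#' @param df A data frame with the columns listed in [read_reservoir_table()].
#' @return The validated tibble.
#' @export
validate_records <- function(df) {
  needed <- c("id", "country", "income_level", "completion_year",
              "reported_area_km2", "resettled_persons",
              "excluded_transboundary", "excluded_preexisting")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("attribute table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
         call. = FALSE)
  }
  bad_income <- setdiff(unique(df$income_level[!is.na(df$income_level)]),
                        INCOME_LEVELS)
  if (length(bad_income)) {
    stop(sprintf("unknown income_level label(s) %s; allowed: %s",
                 paste(sQuote(bad_income), collapse = ", "),
                 paste(INCOME_LEVELS, collapse = ", ")), call. = FALSE)
  }
  df$income_level <- factor(df$income_level, levels = INCOME_LEVELS)
  df$completion_year <- as.integer(df$completion_year)
  df$reported_area_km2 <- as.numeric(df$reported_area_km2)
  df$resettled_persons <- as.numeric(df$resettled_persons)
  df$excluded_transboundary <- as.logical(df$excluded_transboundary)
  df$excluded_preexisting <- as.logical(df$excluded_preexisting)
  if (any(df$reported_area_km2 <= 0, na.rm = TRUE)) {
    stop("reported_area_km2 must be > 0", call. = FALSE)
  }
  if (any(df$resettled_persons < 0, na.rm = TRUE)) {
    stop("resettled_persons must be >= 0", call. = FALSE)
  }
  df
}

#' Match records to polygons and report orphans
#'
#' Records whose ids have no polygon are reported in an audit tibble rather
#' than silently dropped; the full record table is always returned.
#'
#' @param records Tibble from [read_reservoir_table()].
#' @param polygons Tibble from [reservoir_polygons()].
#' @return A list with `records` (unchanged), and `audit`: a tibble
#'   (`id`, `issue`) naming record ids lacking a polygon and polygon ids
#'   lacking a record.
#' @export
match_records_polygons <- function(records, polygons) {
  no_poly <- setdiff(records$id, polygons$id)
  no_rec <- setdiff(polygons$id, records$id)
  audit <- dplyr::bind_rows(
    tibble::tibble(id = no_poly,
                   issue = rep("record without polygon", length(no_poly))),
    tibble::tibble(id = no_rec,
                   issue = rep("polygon without record", length(no_rec)))
  )
  if (nrow(audit)) {
    warning(sprintf("%d unmatched id(s) between records and polygons",
                    nrow(audit)), call. = FALSE)
  }
  list(records = records, audit = audit)
}

#' Write a reservoir attribute table
#'
#' @param records Tibble of records.
#' @param path Output CSV path.
#' @export
write_reservoir_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
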