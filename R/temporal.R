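#' Reference-year selection policy
#'
#' Dam completion marks the moment the reservoir has filled and people have
#' already been relocated, so the population map that represents the
#' situation *before* resettlement must pre-date completion. With maps
#' available at 5-year vintages, the standard policy rounds the completion
#' year down to the second-closest map year, giving a 5–9 year offset —
#' roughly one large-dam construction period. The `late` policy rounds down
#' one vintage further (10–14 years), used as a sensitivity variant.
#'
#' @param mode `"standard"` (offset 5–9 years) or `"late"` (offset 10–14).
#' @param interval_years Spacing of map vintages in years (default 5).
#' @param valid_reference_years Inclusive `c(min, max)` range of available
#'   map years (default 1975–2010).
#' @return A `ref_year_policy` object.
#' @export
reference_year_policy <- function(mode = c("standard", "late"),
                                  interval_years = 5L,
                                  valid_reference_years = c(1975L, 2010L)) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(interval_years), interval_years > 0,
            length(valid_reference_years) == 2,
            valid_reference_years[1] <= valid_reference_years[2])
  structure(
    list(mode = mode,
         interval_years = as.integer(interval_years),
         valid_reference_years = as.integer(valid_reference_years)),
    class = "ref_year_policy"
  )
}

#' Map a dam completion year to a population-map reference year
#'
#' In standard mode the rule is
#' `Y_ref = Y - (k + Y mod k)` with vintage interval `k` (default 5), i.e.
#' the completion year rounded down to the second-closest map year; in late
#' mode one further vintage is subtracted. `mod` is the non-negative
#' remainder. Vectorised over `completion_year`.
#'
#' @param completion_year Integer vector of dam completion years.
#' @param policy A [reference_year_policy()].
#' @return Integer vector of reference years, each divisible by the vintage
#'   interval and inside the policy's valid range.
#' @examples
#' select_reference_year(2008) # 2000
#' select_reference_year(1980) # 1975
#' @export
select_reference_year <- function(completion_year, policy = reference_year_policy()) {
  stopifnot(inherits(policy, "ref_year_policy"))
  y <- as.integer(completion_year)
  k <- policy$interval_years
  offset <- k + (y %% k)
  if (policy$mode == "late") offset <- offset + k
  ref <- y - offset
  rng <- policy$valid_reference_years
  bad <- ref < rng[1] | ref > rng[2]
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf(
      "reference year(s) %s (from completion year(s) %s) fall outside valid range %d-%d",
      paste(ref[which(bad)], collapse = ", "),
      paste(y[which(bad)], collapse = ", "), rng[1], rng[2]),
      call. = FALSE)
  }
  ref
}
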