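#' Bias percentage of predicted vs reported populations
#'
#' `Bias = (sum(p_predicted) - sum(p_reported)) / sum(p_reported) * 100`,
#' a ratio of sums in `[-100, Inf)`. Negative values mean the gridded
#' dataset systematically underestimates the reported population; 0 means no
#' systematic bias. Because it is a ratio of sums, group-wise biases pool
#' exactly: summing numerators and denominators over groups reproduces the
#' global value.
#'
#' @param pairs Tibble with numeric columns `p_reported` and `p_predicted`.
#' @return Bias in percent.
#' @examples
#' bias_percentage(tibble::tibble(p_reported = c(100, 300),
#'                                p_predicted = c(50, 150))) # -50
#' @export
bias_percentage <- function(pairs) {
  check_pairs(pairs)
  denom <- sum(pairs$p_reported)
  if (denom <= 0) {
    stop("bias percentage undefined: sum of reported populations is 0",
         call. = FALSE)
  }
  (sum(pairs$p_predicted) - denom) / denom * 100
}

#' Symmetric mean absolute percentage error (sMAPE)
#'
#' Mean over pairs of `|reported - predicted| / (|reported| + |predicted|)`,
#' in `[0, 1]`: 0 is a perfect prediction, 1 an average error of 100% (e.g.
#' every prediction zero against positive reports). A pair with both values
#' zero is perfect agreement and contributes 0.
#'
#' @inheritParams bias_percentage
#' @return sMAPE in `[0, 1]`.
#' @examples
#' smape(tibble::tibble(p_reported = 100, p_predicted = 50)) # 1/3
#' @export
smape <- function(pairs) {
  check_pairs(pairs)
  if (!nrow(pairs)) stop("sMAPE needs at least one pair", call. = FALSE)
  num <- abs(pairs$p_reported - pairs$p_predicted)
  den <- abs(pairs$p_reported) + abs(pairs$p_predicted)
  terms <- ifelse(den == 0, 0, num / den)
  mean(terms)
}

check_pairs <- function(pairs) {
  if (!all(c("p_reported", "p_predicted") %in% names(pairs))) {
    stop("`pairs` needs columns `p_reported` and `p_predicted`", call. = FALSE)
  }
  if (anyNA(pairs$p_reported) || anyNA(pairs$p_predicted)) {
    stop("NA values in pairs", call. = FALSE)
  }
  invisible(pairs)
}

#' Stratified accuracy summaries
#'
#' Partitions validation pairs by any subset of the stratification keys and
#' computes both accuracy metrics per cell, optionally restricted to a range
#' of map reference years first (used e.g. to compare income levels on a
#' common 2000–2010 period, removing the confound of accuracy drift over
#' time).
#'
#' @param pairs Validation-pair tibble (see [predict_all()]).
#' @param group_keys Character vector among
#'   `c("dataset", "reference_year", "income_level", "country")`; empty for
#'   ungrouped metrics.
#' @param year_range Optional inclusive `c(min, max)` filter on
#'   `reference_year` applied before grouping.
#' @return Tibble with the group key columns plus `bias_percent`, `smape`,
#'   `n`.
#' @export
evaluate_group <- function(pairs, group_keys = "dataset", year_range = NULL) {
  check_pairs(pairs)
  allowed <- c("dataset", "reference_year", "income_level", "country")
  bad <- setdiff(group_keys, allowed)
  if (length(bad)) {
    stop(sprintf("unknown group key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2)
    pairs <- dplyr::filter(pairs, .data$reference_year >= year_range[1],
                           .data$reference_year <= year_range[2])
  }
  if (!nrow(pairs)) stop("no pairs to evaluate", call. = FALSE)
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(
      bias_percent = bias_percentage(dplyr::pick(dplyr::everything())),
      smape = smape(dplyr::pick(dplyr::everything())),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Mean per-country bias across datasets
#'
#' Averages each country's per-dataset bias percentages with equal weight.
#' Countries missing some dataset (no temporal coverage, no pairs) are
#' averaged over the datasets they do have — missing cells are excluded, not
#' zero-filled.
#'
#' @param results Tibble from
#'   `evaluate_group(pairs, c("dataset", "country"))`.
#' @return Tibble `country`, `mean_bias_percent`, `n_datasets`.
#' @export
country_mean_bias <- function(results) {
  stopifnot(all(c("dataset", "country", "bias_percent") %in% names(results)))
  results |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      mean_bias_percent = mean(.data$bias_percent),
      n_datasets = dplyr::n_distinct(.data$dataset),
      .groups = "drop"
    )
}

#' Reported-vs-predicted diagnostic scatter
#'
#' Log-log scatter of predicted against reported populations, one panel per
#' dataset, with the 1:1 line. Pairs with a zero on either axis are dropped
#' from the plot (log scale) with a message.
#'
#' @param pairs Validation-pair tibble.
#' @param colour_by Stratification key used for point colour
#'   (default `"reference_year"`).
#' @return A ggplot object.
#' @export
plot_validation_scatter <- function(pairs, colour_by = "reference_year") {
  check_pairs(pairs)
  keep <- pairs$p_reported > 0 & pairs$p_predicted > 0
  if (any(!keep)) {
    message(sprintf("dropping %d pair(s) with zero counts from log-log plot",
                    sum(!keep)))
  }
  df <- pairs[keep, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$p_reported, .data$p_predicted,
                                   colour = .data[[colour_by]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dataset)) +
    ggplot2::labs(x = "reported population", y = "predicted population") +
    ggplot2::theme_minimal()
}

#' Per-group bias bar chart
#'
#' @param results Tibble from [evaluate_group()].
#' @param x Name of the column to place on the x axis.
#' @return A ggplot object.
#' @export
plot_group_bias <- function(results, x = "dataset") {
  stopifnot("bias_percent" %in% names(results), x %in% names(results))
  ggplot2::ggplot(results, ggplot2::aes(factor(.data[[x]]), .data$bias_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::labs(x = x, y = "bias [%]") +
    ggplot2::theme_minimal()
}
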