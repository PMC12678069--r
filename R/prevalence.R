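#' Country-year prevalence of the six newborn types
#'
#' Converts six-type counts into per-country-year proportions, one row per
#' country-year, with the "small" composite (PT_SGA + PT_AGA + PT_LGA +
#' T_SGA) appended. Proportions are kept at full precision; rows with no
#' records are omitted with a message.
#'
#' @param counts Six-type counts as from [type_counts()] with
#'   `by = c("country_code", "year")`.
#' @return Tibble with `country_code`, `year`, `n`, one proportion column
#'   per type, and `small`. Per-row type proportions sum to 1.
#' @export
country_year_prevalence <- function(counts) {
  prevalence_from_counts(counts, by = c("country_code", "year"))
}

#' National prevalence of the six newborn types
#'
#' Pools counts across all of a country's years (count-weighted, not a mean
#' of yearly proportions), then computes proportions. A year-median variant
#' is available for sensitivity: with `pooling = "year_median"` the national
#' figure is the median of the yearly proportions instead.
#'
#' @param counts Six-type counts per country-year, as from [type_counts()].
#' @param pooling `"counts"` (default) or `"year_median"`.
#' @return Tibble with `country_code`, `n`, one proportion column per type,
#'   and `small`.
#' @export
national_prevalence <- function(counts, pooling = c("counts", "year_median")) {
  pooling <- match.arg(pooling)
  if (pooling == "counts") {
    pooled <- counts |>
      dplyr::group_by(.data$country_code, .data$type) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
    return(prevalence_from_counts(pooled, by = "country_code"))
  }
  cy <- country_year_prevalence(counts)
  cy |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(n = sum(.data$n),
                     dplyr::across(dplyr::all_of(c(TYPE6_LEVELS, "small")),
                                   stats::median),
                     .groups = "drop")
}

prevalence_from_counts <- function(counts, by) {
  totals <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(n_group = sum(.data$n)) |>
    dplyr::ungroup()
  empty <- totals |>
    dplyr::filter(.data$n_group == 0) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(by)))
  if (nrow(empty) > 0) {
    message("prevalence: omitting ", nrow(empty), " group(s) with no records")
  }
  totals |>
    dplyr::filter(.data$n_group > 0) |>
    dplyr::mutate(prop = .data$n / .data$n_group) |>
    dplyr::select(dplyr::all_of(by), "n_group", "type", "prop") |>
    tidyr::pivot_wider(names_from = "type", values_from = "prop",
                       values_fill = 0) |>
    dplyr::rename(n = "n_group") |>
    dplyr::mutate(small = .data$PT_SGA + .data$PT_AGA + .data$PT_LGA +
                    .data$T_SGA)
}

#' Median and interquartile range of a set of prevalences
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the default in mainstream statistical
#' environments); the rule is recorded in the output.
#'
#' @param values Numeric vector (at least one value).
#' @return Tibble with `n`, `q1`, `median`, `q3`, `quantile_rule`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0 || all(is.na(values))) {
    stop("median_iqr: no values", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7,
                       na.rm = TRUE, names = FALSE)
  tibble::tibble(n = sum(!is.na(values)), q1 = q[1], median = q[2], q3 = q[3],
                 quantile_rule = "linear interpolation (type 7)")
}

#' Median/IQR summary of national prevalences, overall and by region
#'
#' Summarises national prevalences of each type (and the small composite)
#' across countries — each national data set weighted equally — within each
#' region and overall.
#'
#' @param national_table Output of [national_prevalence()].
#' @param region_map An [sdg_region_map()] covering every country present
#'   (an unmapped country is an error listing the offending codes).
#' @return Tibble with `region` (including `"overall"`), `type`,
#'   `n_countries`, `q1`, `median`, `q3`.
#' @export
regional_summary <- function(national_table, region_map) {
  region <- region_lookup(region_map, national_table$country_code)
  if (any(region == "unassigned")) {
    stop("regional_summary: unmapped countries: ",
         paste(unique(national_table$country_code[region == "unassigned"]),
               collapse = ", "), call. = FALSE)
  }
  long <- national_table |>
    dplyr::mutate(region = region) |>
    tidyr::pivot_longer(dplyr::all_of(c(TYPE6_LEVELS, "small")),
                        names_to = "type", values_to = "prop")
  summarise_group <- function(df, label) {
    df |>
      dplyr::group_by(.data$type) |>
      dplyr::summarise(n_countries = dplyr::n(),
                       q1 = stats::quantile(.data$prop, 0.25, type = 7, names = FALSE),
                       median = stats::median(.data$prop),
                       q3 = stats::quantile(.data$prop, 0.75, type = 7, names = FALSE),
                       .groups = "drop") |>
      dplyr::mutate(region = label, .before = 1)
  }
  dplyr::bind_rows(
    summarise_group(long, "overall"),
    long |>
      dplyr::group_by(.data$region) |>
      dplyr::group_map(~ summarise_group(.x, .y$region)) |>
      dplyr::bind_rows()
  ) |>
    dplyr::mutate(type = factor(.data$type, levels = c(TYPE6_LEVELS, "small"))) |>
    dplyr::arrange(.data$region != "overall", .data$region, .data$type)
}
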