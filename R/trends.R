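#' Centred 3-year moving average
#'
#' `smoothed(t) = mean(raw(t - 1), raw(t), raw(t + 1))`, defined only when
#' all three consecutive calendar years are present in the series (gaps
#' leave the surrounding years unsmoothed; endpoints are undefined).
#'
#' @param years Integer vector of calendar years (no duplicates).
#' @param values Numeric vector parallel to `years`.
#' @return Numeric vector parallel to the input, `NA` where the centred
#'   window is incomplete.
#' @export
moving_average_3 <- function(years, values) {
  stopifnot(length(years) == length(values), !anyDuplicated(years))
  ord <- order(years)
  years_s <- years[ord]
  values_s <- values[ord]
  prev <- match(years_s - 1L, years_s)
  nxt <- match(years_s + 1L, years_s)
  sm <- (values_s[prev] + values_s + values_s[nxt]) / 3
  sm[is.na(prev) | is.na(nxt)] <- NA_real_
  out <- numeric(length(years))
  out[ord] <- sm
  out
}

#' Eligibility of countries for trend estimation
#'
#' Trends are estimated only for countries contributing at least
#' `min_years` country-years of data.
#'
#' @param country_years Tibble with `country_code` and `year` (one row per
#'   country-year, e.g. a country-year prevalence table).
#' @param min_years Minimum number of distinct years, default 4.
#' @return Tibble with `country_code`, `n_years`, `eligible`.
#' @export
eligible_for_trends <- function(country_years, min_years = 4) {
  country_years |>
    dplyr::distinct(.data$country_code, .data$year) |>
    dplyr::count(.data$country_code, name = "n_years") |>
    dplyr::mutate(eligible = .data$n_years >= min_years)
}

#' Flag trend changes in a smoothed series
#'
#' A year is flagged when the smoothed value moved by strictly more than
#' `threshold_pp` percentage points since the previous consecutive year
#' (both smoothed values defined). A change of exactly the threshold is not
#' flagged.
#'
#' @param years Integer vector of calendar years.
#' @param smoothed Smoothed percentages, as from [moving_average_3()].
#' @param threshold_pp Change threshold in percentage points, default 0.5.
#' @return Logical vector parallel to the input (`FALSE` where undefined).
#' @export
change_flags <- function(years, smoothed, threshold_pp = 0.5) {
  stopifnot(length(years) == length(smoothed))
  ord <- order(years)
  y <- years[ord]
  s <- smoothed[ord]
  prev <- match(y - 1L, y)
  delta <- abs(s - s[prev])
  fl <- !is.na(delta) & delta > threshold_pp
  out <- logical(length(years))
  out[ord] <- fl
  out
}

#' Smoothed trend series of the small and large composites
#'
#' Builds, per eligible country and composite, the annual raw prevalence
#' (percent), a binomial standard-error band on the raw percentage (normal
#' approximation — an explicit uncertainty convention, recorded as such),
#' the centred 3-year moving average and the change flag.
#'
#' @param cy_prevalence Output of [country_year_prevalence()].
#' @param composites Which composites to compute: subset of
#'   `c("small", "large")`; `large` is the T_LGA proportion.
#' @param min_years Eligibility threshold (distinct years per country).
#' @param threshold_pp Change-flag threshold in percentage points.
#' @return Tibble with `country_code`, `composite`, `year`, `n`, `raw_pct`,
#'   `se_pct`, `smoothed_pct`, `change_flag`.
#' @export
trend_series <- function(cy_prevalence, composites = c("small", "large"),
                         min_years = 4, threshold_pp = 0.5) {
  composites <- match.arg(composites, several.ok = TRUE)
  elig <- eligible_for_trends(cy_prevalence, min_years = min_years)
  keep <- elig$country_code[elig$eligible]
  base <- cy_prevalence |>
    dplyr::filter(.data$country_code %in% keep) |>
    dplyr::mutate(large = .data$T_LGA) |>
    dplyr::select("country_code", "year", "n",
                  dplyr::all_of(composites)) |>
    tidyr::pivot_longer(dplyr::all_of(composites), names_to = "composite",
                        values_to = "prop") |>
    dplyr::mutate(raw_pct = 100 * .data$prop,
                  se_pct = 100 * sqrt(.data$prop * (1 - .data$prop) / .data$n))
  base |>
    dplyr::group_by(.data$country_code, .data$composite) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(smoothed_pct = moving_average_3(.data$year, .data$raw_pct),
                  change_flag = change_flags(.data$year, .data$smoothed_pct,
                                             threshold_pp = threshold_pp)) |>
    dplyr::ungroup() |>
    dplyr::select("country_code", "composite", "year", "n", "raw_pct",
                  "se_pct", "smoothed_pct", "change_flag")
}

#' Net change in the smoothed series over fixed periods
#'
#' For each country, composite and period, the net change is the last
#' defined smoothed value minus the first defined smoothed value within the
#' period, with the years actually used recorded. Periods with fewer than
#' two defined smoothed values are reported as undefined (`NA`).
#'
#' @param trend_table Output of [trend_series()].
#' @param periods List of `c(start, end)` year pairs; defaults to the two
#'   decades 2000–2009 and 2010–2021.
#' @return Tibble with `country_code`, `composite`, `period_start`,
#'   `period_end`, `year_first`, `year_last`, `net_change_pp`.
#' @export
period_summary <- function(trend_table,
                           periods = list(c(2000, 2009), c(2010, 2021))) {
  one_period <- function(df, period) {
    def <- df |>
      dplyr::filter(.data$year >= period[1], .data$year <= period[2],
                    !is.na(.data$smoothed_pct)) |>
      dplyr::arrange(.data$year)
    if (nrow(def) < 2) {
      return(tibble::tibble(period_start = period[1], period_end = period[2],
                            year_first = NA_integer_, year_last = NA_integer_,
                            net_change_pp = NA_real_))
    }
    tibble::tibble(period_start = period[1], period_end = period[2],
                   year_first = def$year[1],
                   year_last = def$year[nrow(def)],
                   net_change_pp = def$smoothed_pct[nrow(def)] -
                     def$smoothed_pct[1])
  }
  trend_table |>
    dplyr::group_by(.data$country_code, .data$composite) |>
    dplyr::group_map(function(df, key) {
      dplyr::bind_cols(key[rep(1, length(periods)), ],
                       dplyr::bind_rows(lapply(periods, one_period, df = df)))
    }) |>
    dplyr::bind_rows()
}
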