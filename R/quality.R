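#' Birthweight heaping index at 2500 g
#'
#' Digit-preference diagnostic: the number of births reported at exactly
#' 2500 g divided by the number reported in the 249 g flanks on either side
#' (2250–2499 g and 2501–2750 g). Low values indicate better reporting.
#' Adding or removing records outside 2250–2750 g cannot change the index.
#'
#' @param bw_grams Integer vector of birthweights (missing values ignored).
#' @return The index as a proportion; `NA` when the flank denominator is
#'   empty (undefined, not zero).
#' @examples
#' heaping_index(c(rep(2500, 10), rep(2400, 40), rep(2600, 50))) # 10/90
#' @export
heaping_index <- function(bw_grams) {
  bw <- bw_grams[!is.na(bw_grams)]
  num <- sum(bw == 2500)
  den <- sum((bw >= 2250 & bw <= 2499) | (bw >= 2501 & bw <= 2750))
  if (den == 0) return(NA_real_)
  num / den
}

#' Extreme-tail proportions of birthweight and gestational age
#'
#' Shares of the analysis records with birthweight below 500 g, below
#' 1000 g (strict inequalities), or gestational age up to and including
#' 28 weeks + 6 days (202 days, inclusive). Denominators are records with
#' the relevant variable non-missing.
#'
#' @param records Tibble with `bw_grams` and `ga_days`.
#' @return Named list: `pct_bw_lt_500`, `pct_bw_lt_1000`, `pct_ga_le_28w6d`
#'   (percentages; `NA` on an empty denominator).
#' @export
tail_proportions <- function(records) {
  bw <- records$bw_grams[!is.na(records$bw_grams)]
  ga <- records$ga_days[!is.na(records$ga_days)]
  pct <- function(k, n) if (n == 0) NA_real_ else 100 * k / n
  list(pct_bw_lt_500 = pct(sum(bw < 500), length(bw)),
       pct_bw_lt_1000 = pct(sum(bw < 1000), length(bw)),
       pct_ga_le_28w6d = pct(sum(ga <= 202L), length(ga)))
}

#' Per-variable missingness
#'
#' Missingness is measured on all records received, before the exclusion
#' cascade removes anything.
#'
#' @param records Tibble with `bw_grams`, `ga_days`, `sex`.
#' @return Tibble with `variable`, `n_missing`, `pct_missing`.
#' @export
completeness <- function(records) {
  n <- nrow(records)
  if (n == 0) stop("completeness: no records", call. = FALSE)
  tibble::tibble(
    variable = c("bw", "ga", "sex"),
    n_missing = c(sum(is.na(records$bw_grams)),
                  sum(is.na(records$ga_days)),
                  sum(is.na(records$sex))),
    pct_missing = 100 * .data$n_missing / n
  )
}

#' Country-level inclusion check
#'
#' A country qualifies when coverage of the reference birth population,
#' the facility-birth share, and the completeness of birthweight,
#' gestational age and sex are each at least 80% (all thresholds
#' configurable). Coverage and facility share are external metadata (they
#' come from UN reference estimates), not computed from the records.
#'
#' @param coverage_pct Share of national live births captured (%).
#' @param facility_pct Share of births in healthcare facilities (%).
#' @param completeness_pct Named numeric with elements `bw`, `ga`, `sex`:
#'   completeness (100 - missingness) percentages.
#' @param threshold Qualifying threshold, default 80.
#' @return List with `pass` (logical) and `reasons` (character; empty when
#'   passing). Any missing input yields a fail with reason
#'   `"insufficient metadata"`.
#' @export
inclusion_check <- function(coverage_pct, facility_pct, completeness_pct,
                            threshold = 80) {
  wanted <- c("bw", "ga", "sex")
  if (is.null(coverage_pct) || is.null(facility_pct) ||
      !all(wanted %in% names(completeness_pct)) ||
      anyNA(c(coverage_pct, facility_pct, completeness_pct[wanted]))) {
    return(list(pass = FALSE, reasons = "insufficient metadata"))
  }
  reasons <- character()
  if (coverage_pct < threshold) reasons <- c(reasons, "coverage")
  if (facility_pct < threshold) reasons <- c(reasons, "facility_births")
  for (v in wanted) {
    if (completeness_pct[[v]] < threshold) {
      reasons <- c(reasons, paste0(v, "_completeness"))
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Flag country-years with high missingness for sensitivity analysis
#'
#' Flags every country-year where missingness of birthweight, gestational
#' age or sex exceeds the threshold (strictly more than 20% by default).
#' Downstream prevalence tables can then be recomputed excluding flagged
#' country-years.
#'
#' @param quality_table Per-country-year table with `pct_missing_bw`,
#'   `pct_missing_ga`, `pct_missing_sex` (as from [quality_report()]).
#' @param threshold_pct Flagging threshold in percent, strict.
#' @return The input with a logical `flagged` column appended.
#' @export
sensitivity_filter <- function(quality_table, threshold_pct = 20) {
  dplyr::mutate(
    quality_table,
    flagged = .data$pct_missing_bw > threshold_pct |
      .data$pct_missing_ga > threshold_pct |
      .data$pct_missing_sex > threshold_pct
  )
}

#' Data-quality battery per country-year (or per country)
#'
#' Computes, for each group, the quality metrics used to audit a registry:
#' totals, missingness of the three key variables (measured pre-exclusion),
#' the share excluded as implausible birthweight/gestational-age
#' combinations, extreme-tail proportions and the 2500 g heaping index
#' (both measured on the post-exclusion analysis set).
#'
#' @param records All records received (pre-exclusion).
#' @param exclusions Result of [apply_exclusions()] on `records`; computed
#'   here (with `limits`) when omitted.
#' @param by Grouping columns, default country and year.
#' @param limits Passed to [apply_exclusions()] when `exclusions` is `NULL`.
#' @return Tibble with one row per group: `n_total`, `n_included`,
#'   `pct_missing_bw`, `pct_missing_ga`, `pct_missing_sex`,
#'   `pct_implausible_combo`, `pct_bw_lt_500`, `pct_bw_lt_1000`,
#'   `pct_ga_le_28w6d`, `heaping_index_pct`.
#' @export
quality_report <- function(records, exclusions = NULL,
                           by = c("country_code", "year"),
                           limits = plausibility_limits()) {
  if (is.null(exclusions)) exclusions <- apply_exclusions(records, limits)
  pre <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      pct_missing_bw = 100 * mean(is.na(.data$bw_grams)),
      pct_missing_ga = 100 * mean(is.na(.data$ga_days)),
      pct_missing_sex = 100 * mean(is.na(.data$sex)),
      .groups = "drop"
    )
  combo <- exclusions$excluded |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_combo = sum(.data$reason == "implausible_combo"),
                     .groups = "drop")
  post <- exclusions$included |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_included = dplyr::n(),
      pct_bw_lt_500 = 100 * mean(.data$bw_grams < 500),
      pct_bw_lt_1000 = 100 * mean(.data$bw_grams < 1000),
      pct_ga_le_28w6d = 100 * mean(.data$ga_days <= 202L),
      heaping_index_pct = 100 * heaping_index(.data$bw_grams),
      .groups = "drop"
    )
  pre |>
    dplyr::left_join(combo, by = by) |>
    dplyr::left_join(post, by = by) |>
    dplyr::mutate(
      n_combo = dplyr::coalesce(.data$n_combo, 0L),
      pct_implausible_combo = 100 * .data$n_combo / .data$n_total,
      n_included = dplyr::coalesce(.data$n_included, 0L)
    ) |>
    dplyr::select(dplyr::all_of(by), "n_total", "n_included",
                  "pct_missing_bw", "pct_missing_ga", "pct_missing_sex",
                  "pct_implausible_combo", "pct_bw_lt_500", "pct_bw_lt_1000",
                  "pct_ga_le_28w6d", "heaping_index_pct")
}
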