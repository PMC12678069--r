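#' Plausibility limits for birthweight and gestational age
#'
#' Hard limits defining the plausible window: birthweight plausible in
#' \[250, 6500) grams (250 g inclusive, 6500 g exclusive — a 6500 g record is
#' implausible), gestational age plausible in \[154, 314\] days
#' (22 weeks + 0 days through 44 weeks + 6 days). Records inside the hard
#' limits can still be removed by the joint birthweight/gestational-age
#' envelope (mean +/- `combo_sd_multiplier` SD per completed week).
#'
#' @param bw_min_g Inclusive lower bound of plausible birthweight (g).
#' @param bw_max_g Exclusive upper bound of plausible birthweight (g).
#' @param ga_min_days,ga_max_days Inclusive plausible gestational-age window.
#' @param combo_sd_multiplier SD multiplier of the joint envelope.
#' @param min_cell Minimum records per completed week for the envelope to
#'   define bounds there; sparser weeks yield no combination exclusions.
#' @return An object of class `plausibility_limits`.
#' @export
plausibility_limits <- function(bw_min_g = 250, bw_max_g = 6500,
                                ga_min_days = 154, ga_max_days = 314,
                                combo_sd_multiplier = 5, min_cell = 10) {
  stopifnot(bw_min_g < bw_max_g, ga_min_days < ga_max_days,
            combo_sd_multiplier > 0, min_cell >= 2)
  structure(list(bw_min_g = bw_min_g, bw_max_g = bw_max_g,
                 ga_min_days = ga_min_days, ga_max_days = ga_max_days,
                 combo_sd_multiplier = combo_sd_multiplier,
                 min_cell = min_cell),
            class = "plausibility_limits")
}

#' Birthweight-by-gestational-week plausibility envelope
#'
#' For each completed week of gestation, computes the mean and sample SD of
#' birthweight over the supplied records and sets plausibility bounds at
#' mean +/- `multiplier` * SD. Weeks with fewer than `min_cell` records get
#' undefined (NA) bounds and produce no combination exclusions.
#'
#' @param records Tibble with non-missing `ga_days` and `bw_grams`, already
#'   restricted to the hard plausible window.
#' @param multiplier SD multiplier.
#' @param min_cell Minimum cell size for defined bounds.
#' @return Tibble with `ga_week`, `n`, `mean_bw`, `sd_bw`, `lower`, `upper`.
#' @export
build_envelope <- function(records, multiplier = 5, min_cell = 10) {
  if (nrow(records) == 0) {
    return(tibble::tibble(ga_week = integer(), n = integer(),
                          mean_bw = double(), sd_bw = double(),
                          lower = double(), upper = double()))
  }
  records |>
    dplyr::mutate(ga_week = .data$ga_days %/% 7L) |>
    dplyr::group_by(.data$ga_week) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_bw = mean(.data$bw_grams),
                     sd_bw = stats::sd(.data$bw_grams),
                     .groups = "drop") |>
    dplyr::mutate(
      defined = .data$n >= min_cell & !is.na(.data$sd_bw) & .data$sd_bw > 0,
      lower = ifelse(.data$defined, .data$mean_bw - multiplier * .data$sd_bw, NA_real_),
      upper = ifelse(.data$defined, .data$mean_bw + multiplier * .data$sd_bw, NA_real_)
    ) |>
    dplyr::select(!"defined") |>
    dplyr::arrange(.data$ga_week)
}

EXCLUSION_REASONS <- c("missing_ga", "missing_bw", "missing_both",
                       "missing_sex", "implausible_bw", "implausible_ga",
                       "implausible_combo")

#' Apply the exclusion cascade
#'
#' Removes records that cannot be classified, in a fixed cascade order with
#' single-count accounting (each excluded record carries exactly the first
#' matching reason):
#' 1. `missing_ga` — gestational age missing, birthweight present;
#' 2. `missing_bw` — birthweight missing, gestational age present;
#' 3. `missing_both` — both missing;
#' 4. `missing_sex` — sex missing (values present);
#' 5. `implausible_bw` — outside \[250, 6500) g;
#' 6. `implausible_ga` — outside \[154, 314\] days;
#' 7. `implausible_combo` — birthweight outside the mean +/- 5 SD envelope
#'    for its completed week, the envelope being built from the records
#'    surviving steps 1–6.
#'
#' The flow identity `n_input = n_included + sum(exclusions)` holds exactly.
#'
#' @param records Tibble of canonical birth records.
#' @param limits A [plausibility_limits()].
#' @param envelope Optional pre-built envelope (as from [build_envelope()]);
#'   by default the envelope is rebuilt from the survivors of steps 1–6 of
#'   this run.
#' @return List with `included` (records), `excluded` (records plus a
#'   `reason` column), `flow` (a [flow_accounting()] object) and `envelope`.
#' @export
apply_exclusions <- function(records, limits = plausibility_limits(),
                             envelope = NULL) {
  stopifnot(inherits(limits, "plausibility_limits"))
  n <- nrow(records)
  ga <- records$ga_days
  bw <- records$bw_grams
  sex <- records$sex
  reason <- rep(NA_character_, n)

  miss_ga <- is.na(ga)
  miss_bw <- is.na(bw)
  reason[miss_ga & !miss_bw] <- "missing_ga"
  reason[!miss_ga & miss_bw] <- "missing_bw"
  reason[miss_ga & miss_bw] <- "missing_both"
  reason[is.na(reason) & is.na(sex)] <- "missing_sex"
  reason[is.na(reason) &
           (bw < limits$bw_min_g | bw >= limits$bw_max_g)] <- "implausible_bw"
  reason[is.na(reason) &
           (ga < limits$ga_min_days | ga > limits$ga_max_days)] <- "implausible_ga"

  surv <- is.na(reason)
  if (is.null(envelope)) {
    envelope <- build_envelope(records[surv, , drop = FALSE],
                               multiplier = limits$combo_sd_multiplier,
                               min_cell = limits$min_cell)
  }
  if (nrow(envelope) > 0 && any(surv)) {
    week <- ga %/% 7L
    idx <- match(week, envelope$ga_week)
    lower <- envelope$lower[idx]
    upper <- envelope$upper[idx]
    combo <- surv & !is.na(lower) & (bw < lower | bw > upper)
    reason[combo] <- "implausible_combo"
  }

  keep <- is.na(reason)
  counts <- vapply(EXCLUSION_REASONS, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  flow <- flow_accounting(n_input = n, exclusions = counts)
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(included = records[keep, , drop = FALSE],
       excluded = excluded,
       flow = flow,
       envelope = envelope)
}

#' Flow accounting for data inclusions and exclusions
#'
#' Reconciles the identified input records with the analysis data set:
#' `n_input = n_included + sum(per-reason exclusions)`, exactly, as integers.
#'
#' @param n_input Number of identified records.
#' @param exclusions Named numeric/integer vector of per-reason exclusion
#'   counts, in cascade order.
#' @param n_included Optional; computed from the identity when omitted, and
#'   checked against it when supplied.
#' @return An object of class `flow_accounting`.
#' @export
flow_accounting <- function(n_input, exclusions, n_included = NULL) {
  stopifnot(is.numeric(n_input), length(n_input) == 1, n_input >= 0,
            is.numeric(exclusions), !is.null(names(exclusions)),
            all(exclusions >= 0))
  total_excluded <- sum(exclusions)
  if (is.null(n_included)) {
    n_included <- n_input - total_excluded
  } else if (n_input != n_included + total_excluded) {
    stop("flow_accounting: n_input != n_included + sum(exclusions)",
         call. = FALSE)
  }
  if (n_included < 0) {
    stop("flow_accounting: exclusions exceed input", call. = FALSE)
  }
  structure(list(n_input = n_input,
                 exclusions = tibble::tibble(reason = names(exclusions),
                                             n = unname(exclusions)),
                 n_included = n_included),
            class = "flow_accounting")
}

#' Summarise a flow accounting as counts and percentages of input
#'
#' Each percentage is 100 * count / n_input, reported at one decimal; the
#' table carries the identified input, each exclusion reason in cascade
#' order, the total excluded, and the final included count.
#'
#' @param flow A [flow_accounting()] object.
#' @return Tibble with columns `stage`, `reason`, `n`, `pct_of_input`.
#' @export
flow_summary <- function(flow) {
  stopifnot(inherits(flow, "flow_accounting"))
  if (flow$n_input == 0) {
    stop("flow_summary: n_input is zero", call. = FALSE)
  }
  pct <- function(n) round(100 * n / flow$n_input, 1)
  dplyr::bind_rows(
    tibble::tibble(stage = "input", reason = "identified",
                   n = flow$n_input, pct_of_input = pct(flow$n_input)),
    tibble::tibble(stage = "excluded", reason = flow$exclusions$reason,
                   n = flow$exclusions$n, pct_of_input = pct(flow$exclusions$n)),
    tibble::tibble(stage = "excluded", reason = "total_excluded",
                   n = sum(flow$exclusions$n),
                   pct_of_input = pct(sum(flow$exclusions$n))),
    tibble::tibble(stage = "included", reason = "final_dataset",
                   n = flow$n_included, pct_of_input = pct(flow$n_included))
  )
}
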