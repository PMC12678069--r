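#' Gestational-age class: preterm or term
#'
#' Preterm up to 36 weeks + 6 days (`ga_days <= 258`), term from
#' 37 weeks + 0 days (`ga_days >= 259`).
#'
#' @param ga_days Integer vector of gestational ages in days.
#' @return Factor with levels `PT`, `T`.
#' @export
ga_class <- function(ga_days) {
  factor(ifelse(ga_days <= 258L, "PT", "T"), levels = c("PT", "T"))
}

#' Birthweight class: low birthweight or not
#'
#' LBW strictly below the cutoff; a birthweight of exactly 2500 g is nonLBW
#' (nonLBW is defined as >= 2500 g).
#'
#' @param bw_grams Integer vector of birthweights.
#' @param cutoff_g LBW cutoff in grams.
#' @return Factor with levels `LBW`, `nonLBW`.
#' @export
bw_class <- function(bw_grams, cutoff_g = 2500) {
  factor(ifelse(bw_grams < cutoff_g, "LBW", "nonLBW"),
         levels = c("LBW", "nonLBW"))
}

#' Assign the six-type newborn label
#'
#' The six mutually exclusive types are the cross of gestational-age class
#' (PT/T) and size-for-gestational-age (SGA/AGA/LGA): four small types
#' (PT_SGA, PT_AGA, PT_LGA, T_SGA), one large (T_LGA) and the reference
#' T_AGA.
#'
#' @param ga_days Integer vector of gestational ages in days.
#' @param size_class Factor/character vector of `SGA`/`AGA`/`LGA`.
#' @return Factor over the six type labels.
#' @export
assign_type6 <- function(ga_days, size_class) {
  factor(paste(as.character(ga_class(ga_days)), as.character(size_class),
               sep = "_"),
         levels = TYPE6_LEVELS)
}

#' Assign the ten-type newborn label
#'
#' Splits the six types by the birthweight dimension (LBW/nonLBW). Two of
#' the twelve formal combinations (PT_SGA_nonLBW and T_LGA_LBW) are absent
#' from the conventional ten-type list; they are assigned explicit
#' `unexpected_*` labels and counted, never silently merged, so that
#' conservation checks stay exact.
#'
#' @param type6 Factor/character vector of six-type labels.
#' @param bw_class Factor/character vector of `LBW`/`nonLBW`.
#' @return Factor over the ten labels plus the two `unexpected_*` buckets.
#' @export
assign_type10 <- function(type6, bw_class) {
  lab <- paste(as.character(type6), as.character(bw_class), sep = "_")
  unexpected <- lab %in% c("PT_SGA_nonLBW", "T_LGA_LBW")
  lab[unexpected] <- paste0("unexpected_", lab[unexpected])
  factor(lab, levels = TYPE10_LEVELS)
}

#' Collapse ten-type labels back to six types
#'
#' Drops the birthweight dimension (and any `unexpected_` prefix); the
#' collapse is an exact refinement identity: ten-type counts aggregate to
#' the six-type counts.
#'
#' @param type10 Factor/character vector of ten-type labels.
#' @return Factor over the six type labels.
#' @export
collapse_type10 <- function(type10) {
  lab <- sub("^unexpected_", "", as.character(type10))
  lab <- sub("_(non)?LBW$", "", lab)
  factor(lab, levels = TYPE6_LEVELS)
}

#' Annotate records with all classification dimensions
#'
#' Adds gestational-age class, size-for-gestational-age, birthweight class
#' and the six- and ten-type labels to a set of records that passed the
#' exclusion cascade, plus logical `small` (PT and/or SGA) and `large`
#' (T + LGA) composite indicators.
#'
#' @param records Tibble with non-missing `ga_days`, `bw_grams`, `sex`.
#' @param std A [standard_table()] covering all gestational ages present.
#' @param lbw_cutoff_g LBW cutoff in grams.
#' @return The input tibble with columns `ga_class`, `size_class`,
#'   `bw_class`, `type6`, `type10`, `small`, `large` appended.
#' @export
classify_births <- function(records, std, lbw_cutoff_g = 2500) {
  if (anyNA(records$ga_days) || anyNA(records$bw_grams) || anyNA(records$sex)) {
    stop("classify_births: records contain missing ga/bw/sex; ",
         "run apply_exclusions() first", call. = FALSE)
  }
  records$ga_class <- ga_class(records$ga_days)
  records$size_class <- classify_size(records$bw_grams, records$sex,
                                      records$ga_days, std)
  records$bw_class <- bw_class(records$bw_grams, lbw_cutoff_g)
  records$type6 <- assign_type6(records$ga_days, records$size_class)
  records$type10 <- assign_type10(records$type6, records$bw_class)
  records$small <- records$type6 %in% TYPE6_SMALL
  records$large <- records$type6 == "T_LGA"
  records
}

#' Count newborn types per group
#'
#' Counts are complete over the type levels (zero counts kept), so that
#' per-group counts always sum to the group size and the ten-type table
#' collapses exactly to the six-type table.
#'
#' @param typed Output of [classify_births()].
#' @param by Grouping columns (default country and year).
#' @param dimension `"type6"` or `"type10"`.
#' @return Tibble with the grouping columns, `type` and `n`.
#' @export
type_counts <- function(typed, by = c("country_code", "year"),
                        dimension = c("type6", "type10")) {
  dimension <- match.arg(dimension)
  out <- typed |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), type = .data[[dimension]])
  if (length(by) > 0) {
    out <- tidyr::complete(out, tidyr::nesting(!!!rlang::syms(by)),
                           !!rlang::sym("type"), fill = list(n = 0L))
  } else {
    out <- tidyr::complete(out, !!rlang::sym("type"), fill = list(n = 0L))
  }
  dplyr::mutate(out, n = as.integer(.data$n))
}
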