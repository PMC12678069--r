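#' Construct a size-for-gestational-age centile standard
#'
#' A standard is a table of knots giving, per sex and gestational age in
#' days, the 10th and 90th centile birthweights that define SGA/AGA/LGA.
#' Published newborn size standards (e.g. international size-for-age and
#' sex standards) can be supplied through this contract; the package also
#' ships a synthetic toy family for testing ([make_toy_standard()]).
#'
#' @param knots Data frame with columns `sex` (`"male"`/`"female"`),
#'   `ga_days` (integer), `p10_g`, `p90_g`. Knots must be strictly
#'   increasing in `ga_days` within sex, without duplicates, with
#'   `p10_g < p90_g` everywhere and both sexes covering the same range.
#' @param provenance Free-text label recorded in outputs.
#' @return A tibble of class `standard_table` with attributes `provenance`
#'   and `native_range` (the \[min, max\] `ga_days` covered).
#' @export
standard_table <- function(knots, provenance = "user-supplied") {
  needed <- c("sex", "ga_days", "p10_g", "p90_g")
  if (!all(needed %in% names(knots))) {
    stop("standard_table: need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  knots <- tibble::as_tibble(knots[needed])
  knots$ga_days <- as.integer(knots$ga_days)
  if (!all(knots$sex %in% c("male", "female"))) {
    stop("standard_table: sex must be 'male' or 'female'", call. = FALSE)
  }
  bad <- which(!(knots$p10_g < knots$p90_g))
  if (length(bad) > 0) {
    stop("standard_table: p10 >= p90 at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(knots$p10_g <= 0)) {
    stop("standard_table: non-positive centile weight", call. = FALSE)
  }
  ranges <- list()
  for (s in c("male", "female")) {
    k <- knots[knots$sex == s, ]
    if (nrow(k) < 2) {
      stop("standard_table: need at least two knots for sex ", s, call. = FALSE)
    }
    if (anyDuplicated(k$ga_days)) {
      stop("standard_table: duplicate knots for sex ", s, call. = FALSE)
    }
    if (is.unsorted(k$ga_days, strictly = TRUE)) {
      k <- k[order(k$ga_days), ]
    }
    ranges[[s]] <- range(k$ga_days)
  }
  if (!identical(ranges$male, ranges$female)) {
    stop("standard_table: sexes cover different gestational-age ranges",
         call. = FALSE)
  }
  knots <- knots[order(knots$sex, knots$ga_days), ]
  structure(knots,
            class = c("standard_table", class(tibble::tibble())),
            provenance = provenance,
            native_range = ranges$male)
}

#' Load a centile standard from a delimited file
#'
#' Accepts either day-indexed files (column `ga_days`) or week-indexed files
#' (`ga_weeks`, optionally `ga_extra_days`), converted to days as
#' `7 * weeks + days`. Invariant violations (crossing centiles, duplicate
#' knots) are hard errors.
#'
#' @param path Delimited text file with columns `sex`, `ga_days` (or
#'   `ga_weeks` + optional `ga_extra_days`), `p10_g`, `p90_g`.
#' @param provenance Label recorded in outputs; defaults to the file name.
#' @return A [standard_table()].
#' @export
load_standard <- function(path, provenance = basename(path)) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"ga_days" %in% names(df)) {
    if (!"ga_weeks" %in% names(df)) {
      stop("load_standard: need a ga_days or ga_weeks column", call. = FALSE)
    }
    extra <- if ("ga_extra_days" %in% names(df)) df$ga_extra_days else NULL
    df$ga_days <- normalize_gestational_age(df$ga_weeks, extra)
  }
  standard_table(df, provenance = provenance)
}

#' Centile limits at a given sex and gestational age
#'
#' Returns the 10th and 90th centile birthweights, exactly equal to knot
#' values at knots and linearly interpolated in `ga_days` between knots
#' (independently for each centile; since the 10th lies below the 90th at
#' every knot, linearity preserves the ordering everywhere).
#'
#' @param std A [standard_table()].
#' @param sex Character vector, `"male"`/`"female"`.
#' @param ga_days Integer vector, within the standard's range.
#' @return Tibble with columns `p10_g`, `p90_g`, one row per input.
#' @export
centile_limits <- function(std, sex, ga_days) {
  stopifnot(inherits(std, "standard_table"))
  n <- max(length(sex), length(ga_days))
  sex <- rep_len(sex, n)
  ga_days <- rep_len(as.numeric(ga_days), n)
  if (anyNA(sex) || anyNA(ga_days)) {
    stop("centile_limits: missing sex or gestational age", call. = FALSE)
  }
  rng <- attr(std, "native_range")
  out_of_range <- ga_days < rng[1] | ga_days > rng[2]
  if (any(out_of_range)) {
    stop("centile_limits: gestational age outside the standard's range (",
         rng[1], "-", rng[2], " days) for ", sum(out_of_range),
         " value(s); extend the standard first", call. = FALSE)
  }
  p10 <- numeric(n)
  p90 <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    k <- std[std$sex == s, ]
    p10[i] <- stats::approx(k$ga_days, k$p10_g, xout = ga_days[i],
                            method = "linear", rule = 1)$y
    p90[i] <- stats::approx(k$ga_days, k$p90_g, xout = ga_days[i],
                            method = "linear", rule = 1)$y
  }
  tibble::tibble(p10_g = p10, p90_g = p90)
}

#' Extend a standard beyond its native gestational-age range
#'
#' Published standards often cover a narrower window (e.g. 24 to 42 weeks +
#' 6 days) than the plausible analysis window of 22 weeks + 0 days to
#' 44 weeks + 6 days; the analysis then requires an explicit, labelled
#' extension. `linear_extrapolate` continues the slope of the two outermost
#' knots per sex per centile; `clamp` holds boundary values constant. The
#' extension method is recorded in the table's provenance. Extensions that
#' would produce non-positive weights or crossing centiles are errors.
#'
#' @param std A [standard_table()].
#' @param target_min_days,target_max_days Target range, a superset of the
#'   native range.
#' @param method `"linear_extrapolate"` (default) or `"clamp"`.
#' @return A [standard_table()] covering the target range.
#' @export
extend_standard <- function(std, target_min_days, target_max_days,
                            method = c("linear_extrapolate", "clamp")) {
  stopifnot(inherits(std, "standard_table"))
  method <- match.arg(method)
  rng <- attr(std, "native_range")
  if (target_min_days > rng[1] || target_max_days < rng[2]) {
    stop("extend_standard: target range must contain the native range",
         call. = FALSE)
  }
  extrapolate_at <- function(k, target, side) {
    if (side == "low") {
      x <- k$ga_days[1:2]
      y10 <- k$p10_g[1:2]; y90 <- k$p90_g[1:2]
      at <- function(y) y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (target - x[1])
    } else {
      m <- nrow(k)
      x <- k$ga_days[(m - 1):m]
      y10 <- k$p10_g[(m - 1):m]; y90 <- k$p90_g[(m - 1):m]
      at <- function(y) y[2] + (y[2] - y[1]) / (x[2] - x[1]) * (target - x[2])
    }
    if (method == "clamp") {
      edge <- if (side == "low") 1L else nrow(k)
      c(p10 = k$p10_g[edge], p90 = k$p90_g[edge])
    } else {
      c(p10 = at(y10), p90 = at(y90))
    }
  }
  pieces <- list()
  for (s in c("male", "female")) {
    k <- std[std$sex == s, ]
    add <- list()
    if (target_min_days < rng[1]) {
      v <- extrapolate_at(k, target_min_days, "low")
      add <- c(add, list(tibble::tibble(sex = s, ga_days = target_min_days,
                                        p10_g = v[["p10"]], p90_g = v[["p90"]])))
    }
    if (target_max_days > rng[2]) {
      v <- extrapolate_at(k, target_max_days, "high")
      add <- c(add, list(tibble::tibble(sex = s, ga_days = target_max_days,
                                        p10_g = v[["p10"]], p90_g = v[["p90"]])))
    }
    pieces[[s]] <- dplyr::bind_rows(c(list(tibble::as_tibble(k)), add))
  }
  knots <- dplyr::bind_rows(pieces)
  if (any(knots$p10_g <= 0) || any(knots$p10_g >= knots$p90_g)) {
    stop("extend_standard: extension produced non-positive or crossing ",
         "centiles; use method = \"clamp\" or a wider source table",
         call. = FALSE)
  }
  standard_table(knots,
                 provenance = paste0(attr(std, "provenance"),
                                     "; extended to [", target_min_days, ", ",
                                     target_max_days, "] days by ", method))
}

#' Classify size for gestational age
#'
#' SGA below the 10th centile, LGA above the 90th, AGA otherwise — both
#' centile boundaries classify as AGA (strict inequalities for SGA/LGA).
#'
#' @param bw_grams,sex,ga_days Parallel vectors (no missing values; records
#'   with missing values are removed by the exclusion cascade upstream).
#' @param std A [standard_table()] covering every `ga_days` supplied.
#' @return Factor with levels `SGA`, `AGA`, `LGA`.
#' @export
classify_size <- function(bw_grams, sex, ga_days, std) {
  n <- max(length(bw_grams), length(sex), length(ga_days))
  bw_grams <- rep_len(bw_grams, n)
  lim <- centile_limits(std, rep_len(sex, n), rep_len(ga_days, n))
  out <- rep("AGA", n)
  out[bw_grams < lim$p10_g] <- "SGA"
  out[bw_grams > lim$p90_g] <- "LGA"
  factor(out, levels = c("SGA", "AGA", "LGA"))
}
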