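#' Describe the layout of a registry file
#'
#' A registry schema maps the columns of a delimited birth-registry file onto
#' the canonical record fields, declares how gestational age is encoded, and
#' lists the strings that stand for missing values.
#'
#' @param columns Named list mapping canonical fields to source column names.
#'   Recognised names: `country`, `year`, `bw`, `sex`, and — depending on
#'   `ga_encoding` — `ga_weeks` plus optional `ga_extra_days`, or `ga_days`.
#'   Optional: `plurality`. Unmapped source columns are passed through
#'   untouched.
#' @param ga_encoding How gestational age is stored: `"weeks_plus_days"`
#'   (completed weeks and a 0–6 day remainder in two columns),
#'   `"completed_weeks"` (weeks only; days taken as 0 and the record flagged
#'   as week-resolution), or `"days"` (a single column already in days).
#' @param na_strings Character vector of sentinel strings mapped to missing.
#' @param sex_codes Named list with elements `male` and `female`, each a
#'   character vector of source codes. Non-missing values outside both sets
#'   make the row malformed.
#' @param plurality_codes Named list with elements `singleton` and `multiple`.
#' @param delim Field delimiter of the source file.
#'
#' @return An object of class `registry_schema`.
#' @export
registry_schema <- function(columns = list(country = "country", year = "year",
                                           ga_weeks = "ga_weeks",
                                           ga_extra_days = "ga_extra_days",
                                           bw = "bw_grams", sex = "sex"),
                            ga_encoding = c("weeks_plus_days", "completed_weeks", "days"),
                            na_strings = c("", "NA", "."),
                            sex_codes = list(male = c("male", "M", "m", "1"),
                                             female = c("female", "F", "f", "2")),
                            plurality_codes = list(singleton = c("singleton", "1"),
                                                   multiple = c("multiple", "2", "3", "4")),
                            delim = ",") {
  ga_encoding <- match.arg(ga_encoding)
  required <- c("country", "year", "bw", "sex",
                switch(ga_encoding,
                       weeks_plus_days = "ga_weeks",
                       completed_weeks = "ga_weeks",
                       days = "ga_days"))
  missing_fields <- setdiff(required, names(columns))
  if (length(missing_fields) > 0) {
    stop("registry_schema: missing column mappings for: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  structure(
    list(columns = columns, ga_encoding = ga_encoding, na_strings = na_strings,
         sex_codes = sex_codes, plurality_codes = plurality_codes, delim = delim),
    class = "registry_schema"
  )
}

#' Convert gestational age to days
#'
#' Gestational age is carried internally as days since the last menstrual
#' period: `ga_days = 7 * weeks + days`. Working in days removes every
#' week/day boundary ambiguity — preterm is `ga_days <= 258` (36 weeks +
#' 6 days) and term `ga_days >= 259` (37 weeks + 0 days).
#'
#' @param weeks Integer vector of completed weeks (>= 0).
#' @param days Integer vector of extra days in 0–6, or `NULL` when only
#'   completed weeks are available (days then taken as 0).
#'
#' @return Integer vector of gestational ages in days.
#' @examples
#' normalize_gestational_age(36, 6) # 258, last preterm day
#' normalize_gestational_age(37, 0) # 259, first term day
#' @export
normalize_gestational_age <- function(weeks, days = NULL) {
  weeks <- as.integer(weeks)
  if (is.null(days)) days <- 0L
  days <- as.integer(days)
  bad <- !is.na(days) & (days < 0L | days > 6L)
  if (any(bad)) {
    stop("normalize_gestational_age: days component outside 0-6 for ",
         sum(bad), " value(s)", call. = FALSE)
  }
  if (any(!is.na(weeks) & weeks < 0L)) {
    stop("normalize_gestational_age: negative weeks", call. = FALSE)
  }
  out <- 7L * weeks + days
  out[is.na(weeks)] <- NA_integer_
  out
}

# Strict integer parse: NA for anything that is not an optionally signed
# string of digits. as.integer("3.5") would silently truncate, hence regex.
parse_strict_int <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & grepl("^[+-]?[0-9]+$", x)
  out[ok] <- as.integer(x[ok])
  out
}

#' Read and normalize a birth-registry file
#'
#' Reads a delimited text file, applies a [registry_schema()], and returns
#' canonical birth records together with a parse report. Well-formed rows
#' yield exactly one record each, in file order; rows with unparseable or
#' out-of-contract values (non-integer weights, a days-of-week field outside
#' 0–6, an unrecognised sex code, ...) are counted as malformed and dropped.
#' Malformed rows are reported separately from the downstream exclusion
#' cascade, which only ever sees well-formed records.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [registry_schema()].
#'
#' @return A list with `records` (a tibble of canonical birth records:
#'   `country_code`, `year`, `ga_days`, `ga_week_resolution`, `bw_grams`,
#'   `sex`, optional `plurality`, plus pass-through columns) and
#'   `parse_report` (list with `n_rows`, `n_records`, `n_malformed` and a
#'   per-reason breakdown; `n_rows = n_records + n_malformed` always).
#' @export
read_registry <- function(path, schema = registry_schema()) {
  if (!inherits(schema, "registry_schema")) {
    stop("read_registry: `schema` must be a registry_schema object", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("read_registry: file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = schema$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  mapped <- unlist(schema$columns, use.names = FALSE)
  absent <- setdiff(mapped, names(raw))
  if (length(absent) > 0) {
    stop("read_registry: mapped column(s) not in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  col <- function(field) {
    nm <- schema$columns[[field]]
    if (is.null(nm)) return(NULL)
    x <- raw[[nm]]
    x[x %in% schema$na_strings] <- NA_character_
    x
  }

  bad <- rep(FALSE, n)
  why <- rep(NA_character_, n)
  flag <- function(cond, reason) {
    new <- cond & !bad
    why[new] <<- reason
    bad[new] <<- TRUE
  }

  country <- col("country")
  yr_raw <- col("year")
  year <- parse_strict_int(yr_raw)
  flag(!is.na(yr_raw) & is.na(year), "bad_year")
  flag(is.na(yr_raw), "bad_year")

  bw_raw <- col("bw")
  bw <- parse_strict_int(bw_raw)
  flag(!is.na(bw_raw) & is.na(bw), "bad_birthweight")
  flag(!is.na(bw) & bw <= 0L, "bad_birthweight")
  bw[!is.na(bw) & bw <= 0L] <- NA_integer_

  week_res <- FALSE
  if (schema$ga_encoding == "days") {
    gad_raw <- col("ga_days")
    ga_days <- parse_strict_int(gad_raw)
    flag(!is.na(gad_raw) & is.na(ga_days), "bad_gestational_age")
    flag(!is.na(ga_days) & ga_days < 0L, "bad_gestational_age")
  } else {
    gw_raw <- col("ga_weeks")
    gw <- parse_strict_int(gw_raw)
    flag(!is.na(gw_raw) & is.na(gw), "bad_gestational_age")
    flag(!is.na(gw) & gw < 0L, "bad_gestational_age")
    if (schema$ga_encoding == "weeks_plus_days" &&
        !is.null(schema$columns$ga_extra_days)) {
      gd_raw <- col("ga_extra_days")
      gd <- parse_strict_int(gd_raw)
      flag(!is.na(gd_raw) & is.na(gd), "bad_gestational_age")
      flag(!is.na(gd) & (gd < 0L | gd > 6L), "bad_gestational_age")
      gd[is.na(gd)] <- 0L
    } else {
      gd <- 0L
      week_res <- TRUE
    }
    ga_days <- 7L * gw + rep(gd, length.out = n)
    ga_days[is.na(gw)] <- NA_integer_
    ga_days[bad] <- NA_integer_
  }

  sex_raw <- col("sex")
  sex <- rep(NA_character_, n)
  sex[sex_raw %in% schema$sex_codes$male] <- "male"
  sex[sex_raw %in% schema$sex_codes$female] <- "female"
  flag(!is.na(sex_raw) & is.na(sex), "bad_sex_code")

  records <- tibble::tibble(
    country_code = as.character(country),
    year = year,
    ga_days = as.integer(ga_days),
    ga_week_resolution = week_res,
    bw_grams = bw,
    sex = sex
  )
  if (!is.null(schema$columns$plurality)) {
    pl_raw <- col("plurality")
    pl <- rep(NA_character_, n)
    pl[pl_raw %in% schema$plurality_codes$singleton] <- "singleton"
    pl[pl_raw %in% schema$plurality_codes$multiple] <- "multiple"
    records$plurality <- pl
  }
  passthrough <- setdiff(names(raw), mapped)
  for (nm in passthrough) records[[nm]] <- raw[[nm]]

  records <- records[!bad, , drop = FALSE]
  reasons <- table(why[bad])
  parse_report <- list(
    n_rows = n,
    n_records = nrow(records),
    n_malformed = sum(bad),
    reasons = tibble::tibble(reason = names(reasons), n = as.integer(reasons))
  )
  list(records = records, parse_report = parse_report)
}

#' Write an output table as delimited text
#'
#' All tabular outputs are written as plain comma-delimited text with a
#' header. Values are written at full precision so that reading the file
#' back yields a value-identical table.
#'
#' @param rows A data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' Map countries to summary regions
#'
#' Builds a lookup from country code to the regional grouping used in
#' aggregate summaries (the study design uses four Sustainable Development
#' Goal regions). Countries absent from the map receive the explicit label
#' `"unassigned"` so that the lookup is total.
#'
#' @param country_code,region Parallel character vectors.
#' @return A tibble with class `sdg_region_map`.
#' @export
sdg_region_map <- function(country_code, region) {
  if (anyDuplicated(country_code)) {
    stop("sdg_region_map: duplicated country codes", call. = FALSE)
  }
  out <- tibble::tibble(country_code = as.character(country_code),
                        region = as.character(region))
  class(out) <- c("sdg_region_map", class(out))
  out
}

#' Look up regions for a set of countries
#'
#' @param map An [sdg_region_map()].
#' @param country_code Character vector of codes to resolve.
#' @return Character vector of region labels, `"unassigned"` where unmapped.
#' @export
region_lookup <- function(map, country_code) {
  idx <- match(country_code, map$country_code)
  out <- map$region[idx]
  out[is.na(idx)] <- "unassigned"
  out
}
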