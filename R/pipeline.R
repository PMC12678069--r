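#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the input records (either
#' in-memory records or paths plus schemas), the centile standard and how to
#' extend it to the plausible window, plausibility limits, the region map,
#' the sensitivity toggle and trend settings, and an output directory for
#' the written tables.
#'
#' @param records In-memory canonical records (tibble), or `NULL` to read
#'   from `inputs`.
#' @param inputs List of `list(path = , schema = )` entries read with
#'   [read_registry()] and row-bound. Ignored when `records` is given.
#' @param standard A [standard_table()] or a path for [load_standard()].
#' @param extension_method Passed to [extend_standard()] when the standard
#'   does not cover the plausible window.
#' @param limits A [plausibility_limits()].
#' @param region_map An [sdg_region_map()], a path to a two-column
#'   (country_code, region) file, or `NULL` to skip regional summaries.
#' @param sensitivity Recompute prevalences excluding country-years with
#'   more than `sensitivity_threshold_pct` missingness?
#' @param sensitivity_threshold_pct Missingness threshold (strict), percent.
#' @param trend_threshold_pp Change-flag threshold in percentage points.
#' @param trend_min_years Minimum country-years for trend eligibility.
#' @param periods Periods for [period_summary()].
#' @param out_dir Directory for written outputs, or `NULL` to keep results
#'   in memory only.
#' @param per_record_output Write the per-record typed table? Off by
#'   default: outputs are aggregate-only unless explicitly requested.
#' @param suppress_small_cells Mask aggregated counts below 5 in written
#'   tables (disclosure control for registries that require it).
#' @param seed Recorded in the manifest (the core pipeline is
#'   deterministic; the seed governs any resampling extension).
#' @return An object of class `run_config`.
#' @export
run_config <- function(records = NULL, inputs = NULL,
                       standard = make_toy_standard(),
                       extension_method = "linear_extrapolate",
                       limits = plausibility_limits(),
                       region_map = NULL,
                       sensitivity = TRUE, sensitivity_threshold_pct = 20,
                       trend_threshold_pp = 0.5, trend_min_years = 4,
                       periods = list(c(2000, 2009), c(2010, 2021)),
                       out_dir = NULL, per_record_output = FALSE,
                       suppress_small_cells = FALSE, seed = 1L) {
  structure(list(records = records, inputs = inputs, standard = standard,
                 extension_method = extension_method, limits = limits,
                 region_map = region_map, sensitivity = sensitivity,
                 sensitivity_threshold_pct = sensitivity_threshold_pct,
                 trend_threshold_pp = trend_threshold_pp,
                 trend_min_years = trend_min_years, periods = periods,
                 out_dir = out_dir, per_record_output = per_record_output,
                 suppress_small_cells = suppress_small_cells,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration before touching any data
#'
#' Checks file references and numeric ranges and returns every violation
#' found (not just the first).
#'
#' @param config A [run_config()].
#' @return Tibble with columns `field` and `problem`; zero rows when valid.
#' @export
validate_config <- function(config) {
  problems <- list()
  note <- function(field, problem) {
    problems[[length(problems) + 1]] <<- tibble::tibble(field = field,
                                                        problem = problem)
  }
  if (is.null(config$records) && is.null(config$inputs)) {
    note("records", "no records and no inputs supplied")
  }
  for (inp in config$inputs %||% list()) {
    if (is.null(inp$path) || !file.exists(inp$path)) {
      note("inputs", paste0("input file not found: ",
                            inp$path %||% "<missing path>"))
    }
    if (!inherits(inp$schema %||% registry_schema(), "registry_schema")) {
      note("inputs", "schema is not a registry_schema")
    }
  }
  if (is.character(config$standard) && !file.exists(config$standard)) {
    note("standard", paste0("standard file not found: ", config$standard))
  }
  if (is.character(config$region_map) && !file.exists(config$region_map)) {
    note("region_map", paste0("region map file not found: ", config$region_map))
  }
  if (!inherits(config$limits, "plausibility_limits")) {
    note("limits", "not a plausibility_limits object")
  }
  if (config$trend_threshold_pp < 0) {
    note("trend_threshold_pp", "must be non-negative")
  }
  if (config$sensitivity_threshold_pct < 0 ||
      config$sensitivity_threshold_pct > 100) {
    note("sensitivity_threshold_pct", "must be in [0, 100]")
  }
  if (config$trend_min_years < 1) note("trend_min_years", "must be >= 1")
  if (length(problems) == 0) {
    return(tibble::tibble(field = character(), problem = character()))
  }
  dplyr::bind_rows(problems)
}

#' Run the full analysis pipeline
#'
#' Orchestrates read, quality assessment, exclusion cascade, type
#' classification, prevalence aggregation and trend estimation from one
#' configuration; optionally writes every output table plus a run manifest
#' recording versions, settings and conventions (quantile rule, standard
#' extension) for reproducibility.
#'
#' @param config A [run_config()] (validated first; any problem aborts).
#' @return (Invisibly) a list with `flow`, `flow_table`, `quality`,
#'   `prevalence_country_year`, `prevalence_national`, `summary_regional`
#'   (when a region map is given), `trends`, `trend_periods`, `sensitivity`
#'   (flagged table and re-computed prevalences, when toggled), `typed`
#'   (when `per_record_output`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  problems <- validate_config(config)
  if (nrow(problems) > 0) {
    stop("run_pipeline: invalid configuration:\n",
         paste0("  - ", problems$field, ": ", problems$problem,
                collapse = "\n"), call. = FALSE)
  }

  records <- config$records
  if (is.null(records)) {
    reads <- lapply(config$inputs, function(inp) {
      read_registry(inp$path, inp$schema %||% registry_schema())
    })
    records <- dplyr::bind_rows(lapply(reads, `[[`, "records"))
  }

  std <- config$standard
  if (is.character(std)) std <- load_standard(std)
  rng <- attr(std, "native_range")
  want <- c(config$limits$ga_min_days, config$limits$ga_max_days)
  if (rng[1] > want[1] || rng[2] < want[2]) {
    std <- extend_standard(std, min(rng[1], want[1]), max(rng[2], want[2]),
                           method = config$extension_method)
  }

  excl <- apply_exclusions(records, config$limits)
  flow_table <- flow_summary(excl$flow)
  quality <- quality_report(records, exclusions = excl)

  typed <- classify_births(excl$included, std)
  counts6 <- type_counts(typed, by = c("country_code", "year"),
                         dimension = "type6")
  counts10 <- type_counts(typed, by = c("country_code", "year"),
                          dimension = "type10")
  cy_prev <- country_year_prevalence(counts6)
  nat_prev <- national_prevalence(counts6)

  region_map <- config$region_map
  if (is.character(region_map)) {
    rm_df <- readr::read_csv(region_map, show_col_types = FALSE)
    region_map <- sdg_region_map(rm_df$country_code, rm_df$region)
  }
  summary_regional <- if (!is.null(region_map)) {
    regional_summary(nat_prev, region_map)
  }

  trends <- trend_series(cy_prev, min_years = config$trend_min_years,
                         threshold_pp = config$trend_threshold_pp)
  trend_periods <- period_summary(trends, periods = config$periods)

  sensitivity <- NULL
  if (isTRUE(config$sensitivity)) {
    flagged <- sensitivity_filter(quality,
                                  threshold_pct = config$sensitivity_threshold_pct)
    drop <- flagged[flagged$flagged, c("country_code", "year")]
    counts6_sub <- dplyr::anti_join(counts6, drop,
                                    by = c("country_code", "year"))
    sensitivity <- list(
      flagged_country_years = flagged,
      n_flagged = nrow(drop),
      prevalence_country_year = country_year_prevalence(counts6_sub),
      prevalence_national = national_prevalence(counts6_sub)
    )
  }

  manifest <- list(
    package = "newborntypes",
    version = as.character(utils::packageVersion("newborntypes")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_input = excl$flow$n_input,
    n_included = excl$flow$n_included,
    standard_provenance = attr(std, "provenance"),
    extension_method = config$extension_method,
    quantile_rule = "linear interpolation (type 7)",
    trend_threshold_pp = config$trend_threshold_pp,
    trend_min_years = config$trend_min_years,
    sensitivity_threshold_pct = config$sensitivity_threshold_pct,
    lbw_cutoff_g = 2500,
    limits = unclass(config$limits)
  )

  result <- list(flow = excl$flow, flow_table = flow_table,
                 quality = quality, counts6 = counts6, counts10 = counts10,
                 prevalence_country_year = cy_prev,
                 prevalence_national = nat_prev,
                 summary_regional = summary_regional,
                 trends = trends, trend_periods = trend_periods,
                 sensitivity = sensitivity, manifest = manifest)
  if (isTRUE(config$per_record_output)) result$typed <- typed

  if (!is.null(config$out_dir)) {
    write_outputs(result, config)
  }
  invisible(result)
}

mask_small_cells <- function(counts, threshold = 5) {
  counts$n[counts$n > 0 & counts$n < threshold] <- NA_integer_
  counts
}

write_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(config$out_dir, name)
    write_table(df, path)
    written <<- c(written, path)
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  counts6 <- result$counts6
  counts10 <- result$counts10
  if (isTRUE(config$suppress_small_cells)) {
    counts6 <- mask_small_cells(counts6)
    counts10 <- mask_small_cells(counts10)
  }
  emit(result$flow_table, "flow.csv")
  emit(result$quality, "quality.csv")
  emit(counts6, "counts_type6.csv")
  emit(counts10, "counts_type10.csv")
  emit(result$prevalence_country_year, "prevalence_country_year.csv")
  emit(result$prevalence_national, "prevalence_national.csv")
  emit(result$summary_regional, "summary_regional.csv")
  emit(result$trends, "trends.csv")
  emit(result$trend_periods, "trend_periods.csv")
  if (!is.null(result$sensitivity)) {
    emit(result$sensitivity$flagged_country_years, "sensitivity_flags.csv")
    emit(result$sensitivity$prevalence_country_year,
         "sensitivity_prevalence_country_year.csv")
    emit(result$sensitivity$prevalence_national,
         "sensitivity_prevalence_national.csv")
  }
  if (!is.null(result$typed)) emit(result$typed, "typed_records.csv")
  manifest <- result$manifest
  manifest$written <- basename(written)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  ok <- TRUE
  invisible(written)
}
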