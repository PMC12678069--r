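# Shared fixtures built in code.

# Quick record builder with sensible defaults.
births <- function(ga_days = 280L, bw_grams = 3300L, sex = "male",
                   country_code = "AA", year = 2015L, ...) {
  tibble::tibble(country_code = country_code, year = as.integer(year),
                 ga_days = as.integer(ga_days),
                 ga_week_resolution = FALSE,
                 bw_grams = as.integer(bw_grams), sex = sex, ...)
}

# Flat Gaussian toy standard: mean 3000 g, SD 400 g at every gestational
# age, no sex offset. p10/p90 are the 10%/90% normal quantiles.
flat_growth <- function(mean_g = 3000, sd_g = 400) {
  g <- newborntypes::toy_growth_params(sex_offset_g = 0)
  g$mean_fun <- function(ga) rep(mean_g, length(ga))
  g$sd_fun <- function(ga) rep(sd_g, length(ga))
  g
}

flat_standard <- function(mean_g = 3000, sd_g = 400) {
  newborntypes::make_toy_standard(growth = flat_growth(mean_g, sd_g))
}

# Write a small registry CSV and return its path (under the session tempdir).
write_registry_fixture <- function(lines) {
  path <- tempfile("registry", fileext = ".csv")
  writeLines(lines, path)
  path
}
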