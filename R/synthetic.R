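#' Default growth parameters of the toy Gaussian family
#'
#' The toy family models birthweight given gestational age and sex as
#' Gaussian with a piecewise-linear mean (rapid fetal growth to 40 weeks,
#' a flatter slope after) and a linearly widening SD; males sit a constant
#' offset above females. Both pieces break only at day 280, which is a
#' weekly knot, so the weekly-knot standard built from this family
#' interpolates it exactly at day resolution.
#'
#' @param sex_offset_g Male minus female mean weight, grams.
#' @return List with functions `mean_fun(ga_days)` (female mean),
#'   `sd_fun(ga_days)` and the scalar `sex_offset_g`.
#' @export
toy_growth_params <- function(sex_offset_g = 100) {
  list(
    mean_fun = function(ga_days) {
      ifelse(ga_days <= 280,
             500 + (ga_days - 154) * (3300 - 500) / (280 - 154),
             3300 + (ga_days - 280) * 10)
    },
    sd_fun = function(ga_days) 110 + 2 * (ga_days - 154),
    sex_offset_g = sex_offset_g
  )
}

#' Build a toy centile standard from a Gaussian-by-week family
#'
#' Computes 10th/90th centile knots at every completed week over the
#' plausible window (plus the terminal day) from the family's normal
#' quantiles: `p10 = mean + qnorm(0.1) * sd`, `p90 = mean + qnorm(0.9) * sd`.
#' This synthetic standard exists for testing and demonstration; published
#' standards are supplied through [load_standard()] instead.
#'
#' @param family Only `"gaussian_by_week"` is implemented.
#' @param growth Growth parameters, as from [toy_growth_params()].
#' @param ga_range Days covered, default the full plausible window 154–314.
#' @return A [standard_table()] labelled as synthetic.
#' @examples
#' # Constant mean 3000 g / SD 400 g: p10 ~ 2487.4 g, p90 ~ 3512.6 g
#' flat <- toy_growth_params(sex_offset_g = 0)
#' flat$mean_fun <- function(ga) rep(3000, length(ga))
#' flat$sd_fun <- function(ga) rep(400, length(ga))
#' std <- make_toy_standard(growth = flat)
#' @export
make_toy_standard <- function(family = "gaussian_by_week",
                              growth = toy_growth_params(),
                              ga_range = c(154, 314)) {
  family <- match.arg(family)
  days <- unique(c(seq(ga_range[1], ga_range[2], by = 7L), ga_range[2]))
  sdv <- growth$sd_fun(days)
  if (any(sdv <= 0)) stop("make_toy_standard: scale <= 0", call. = FALSE)
  knots <- dplyr::bind_rows(lapply(c("male", "female"), function(s) {
    mu <- growth$mean_fun(days) + if (s == "male") growth$sex_offset_g else 0
    tibble::tibble(sex = s, ga_days = as.integer(days),
                   p10_g = stats::qnorm(0.1, mu, sdv),
                   p90_g = stats::qnorm(0.9, mu, sdv))
  }))
  standard_table(knots, provenance = paste0("synthetic: ", family))
}

#' Specify one synthetic country
#'
#' Per-country knobs of the generator: observation years, annual volume,
#' sex ratio, the gestational-age law (a term Gaussian component plus a
#' bounded preterm tail, so preterm and SGA rates tune independently) and
#' target SGA/LGA rates. The SGA/LGA targets are met by drawing the
#' birthweight z-score (relative to the toy standard's family) from
#' `N(m, c^2)` with `m`, `c` solved in closed form so that
#' `P(z < qnorm(0.1)) = sga_rate` and `P(z > qnorm(0.9)) = lga_rate`.
#'
#' @param country_code Country identifier.
#' @param years Integer vector of calendar years.
#' @param births_per_year Births generated per year.
#' @param sex_ratio_male Probability of male sex.
#' @param preterm_rate Target proportion of preterm (<= 258 days) births.
#' @param sga_rate,lga_rate Target SGA/LGA proportions at every
#'   gestational age (must satisfy `sga_rate + lga_rate < 1`).
#' @param ga_term_mean_days,ga_term_sd_days Term gestational-age component.
#' @param ga_preterm_shape,ga_preterm_scale Gamma-distributed days below
#'   259 for the preterm tail (bounded to the plausible window).
#' @param missing_bw,missing_ga,missing_sex Optional country-level
#'   missingness overrides (default: inherit the generator-wide rates).
#' @return An object of class `country_spec`.
#' @export
country_spec <- function(country_code, years, births_per_year,
                         sex_ratio_male = 0.515,
                         preterm_rate = 0.07, sga_rate = 0.10, lga_rate = 0.10,
                         ga_term_mean_days = 280, ga_term_sd_days = 8,
                         ga_preterm_shape = 2, ga_preterm_scale = 10,
                         missing_bw = NULL, missing_ga = NULL,
                         missing_sex = NULL) {
  stopifnot(length(years) >= 1, births_per_year >= 1,
            sex_ratio_male >= 0, sex_ratio_male <= 1,
            preterm_rate >= 0, preterm_rate <= 1,
            sga_rate >= 0, lga_rate >= 0)
  if (sga_rate + lga_rate >= 1) {
    stop("country_spec: sga_rate + lga_rate must be < 1 (infeasible ",
         "size-for-gestational-age targets)", call. = FALSE)
  }
  structure(list(country_code = country_code, years = as.integer(years),
                 births_per_year = births_per_year,
                 sex_ratio_male = sex_ratio_male,
                 preterm_rate = preterm_rate,
                 sga_rate = sga_rate, lga_rate = lga_rate,
                 ga_term_mean_days = ga_term_mean_days,
                 ga_term_sd_days = ga_term_sd_days,
                 ga_preterm_shape = ga_preterm_shape,
                 ga_preterm_scale = ga_preterm_scale,
                 missing_bw = missing_bw, missing_ga = missing_ga,
                 missing_sex = missing_sex),
            class = "country_spec")
}

#' Configure the synthetic registry generator
#'
#' Bundles country specifications, the standard used for ground-truth
#' typing, corruption rates and the mandatory seed. Corruptions are applied
#' after truth labelling, in the fixed order heaping, round-to-100,
#' missingness, implausible-record injection.
#'
#' @param countries List of [country_spec()] objects.
#' @param standard The [standard_table()] used to compute truth labels (by
#'   default the toy standard over the same growth family the weights are
#'   drawn from, so truth and pipeline classification agree exactly).
#' @param growth Growth family parameters, as from [toy_growth_params()].
#' @param missing_bw,missing_ga,missing_sex Generator-wide missingness
#'   rates in \[0, 1\] (overridable per country).
#' @param heaping_fraction Share of records with true birthweight in the
#'   2250–2750 g window relocated to exactly 2500 g.
#' @param round100_fraction Share of (unheaped) records rounded to the
#'   nearest 100 g.
#' @param implausible_bw_rate,implausible_ga_rate,implausible_combo_rate
#'   Injection rates of hard-limit-violating birthweights/gestational ages
#'   and of in-window weights far outside the weekly envelope.
#' @param seed Mandatory integer seed; the same seed reproduces the output
#'   exactly.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(countries,
                             standard = make_toy_standard(),
                             growth = toy_growth_params(),
                             missing_bw = 0, missing_ga = 0, missing_sex = 0,
                             heaping_fraction = 0, round100_fraction = 0,
                             implausible_bw_rate = 0, implausible_ga_rate = 0,
                             implausible_combo_rate = 0,
                             seed) {
  if (missing(seed)) stop("generator_config: seed is mandatory", call. = FALSE)
  if (inherits(countries, "country_spec")) countries <- list(countries)
  stopifnot(all(vapply(countries, inherits, logical(1), "country_spec")))
  rates <- c(missing_bw, missing_ga, missing_sex, heaping_fraction,
             round100_fraction, implausible_bw_rate, implausible_ga_rate,
             implausible_combo_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("generator_config: all rates must be in [0, 1]", call. = FALSE)
  }
  structure(list(countries = countries, standard = standard, growth = growth,
                 missing_bw = missing_bw, missing_ga = missing_ga,
                 missing_sex = missing_sex,
                 heaping_fraction = heaping_fraction,
                 round100_fraction = round100_fraction,
                 implausible_bw_rate = implausible_bw_rate,
                 implausible_ga_rate = implausible_ga_rate,
                 implausible_combo_rate = implausible_combo_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# z-score law N(m, c^2) hitting P(z < qnorm(.1)) = sga and
# P(z > qnorm(.9)) = lga.
z_law <- function(sga_rate, lga_rate) {
  z10 <- stats::qnorm(0.10)
  z90 <- stats::qnorm(0.90)
  qs <- stats::qnorm(sga_rate)
  ql <- stats::qnorm(1 - lga_rate)
  if (!is.finite(qs) || !is.finite(ql) || ql <= qs) {
    stop("infeasible SGA/LGA targets", call. = FALSE)
  }
  c_scale <- (z90 - z10) / (ql - qs)
  list(m = z10 - c_scale * qs, c = c_scale)
}

#' Generate a synthetic multi-country birth registry with ground truth
#'
#' Draws records country by country (sex, gestational age from the
#' term-plus-preterm-tail mixture, birthweight from the Gaussian growth
#' family with the country's z-score law), computes ground-truth type
#' labels against the configured standard on the uncorrupted values, then
#' applies corruptions in order: heaping, round-to-100, missingness,
#' implausible-record injection. Deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return List with `records` (canonical birth records, corrupted),
#'   `truth` (per-record true labels and defect tags, keyed by
#'   `record_id`) and `config`.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  growth <- config$growth
  std <- config$standard
  pieces <- lapply(config$countries, function(cs) {
    n <- cs$births_per_year * length(cs$years)
    year <- rep(cs$years, each = cs$births_per_year)
    sex <- ifelse(stats::runif(n) < cs$sex_ratio_male, "male", "female")
    is_pt <- stats::runif(n) < cs$preterm_rate
    ga <- integer(n)
    n_pt <- sum(is_pt)
    if (n_pt > 0) {
      ga[is_pt] <- pmax(154L, pmin(258L, 258L - as.integer(round(
        stats::rgamma(n_pt, shape = cs$ga_preterm_shape,
                      scale = cs$ga_preterm_scale)))))
    }
    if (n_pt < n) {
      ga[!is_pt] <- pmax(259L, pmin(314L, as.integer(round(
        stats::rnorm(n - n_pt, cs$ga_term_mean_days, cs$ga_term_sd_days)))))
    }
    zl <- z_law(cs$sga_rate, cs$lga_rate)
    z <- zl$m + zl$c * stats::rnorm(n)
    mu <- growth$mean_fun(ga) + ifelse(sex == "male", growth$sex_offset_g, 0)
    sdv <- growth$sd_fun(ga)
    bw <- as.integer(pmax(250, pmin(6499, round(mu + sdv * z))))
    plurality <- ifelse(stats::runif(n) < 0.03, "multiple", "singleton")
    tibble::tibble(country_code = cs$country_code, year = year,
                   ga_days = ga, bw_grams = bw, sex = sex,
                   plurality = plurality, mu = mu, sdv = sdv,
                   missing_bw_rate = cs$missing_bw %||% config$missing_bw,
                   missing_ga_rate = cs$missing_ga %||% config$missing_ga,
                   missing_sex_rate = cs$missing_sex %||% config$missing_sex)
  })
  df <- dplyr::bind_rows(pieces)
  n <- nrow(df)
  df$record_id <- seq_len(n)

  # Ground truth against the same standard the pipeline will use,
  # computed before any corruption.
  size <- classify_size(df$bw_grams, df$sex, df$ga_days, std)
  type6 <- assign_type6(df$ga_days, size)
  type10 <- assign_type10(type6, bw_class(df$bw_grams))
  truth <- tibble::tibble(
    record_id = df$record_id,
    country_code = df$country_code,
    year = df$year,
    true_size_class = size,
    true_type6 = type6,
    true_type10 = type10,
    true_small = type6 %in% TYPE6_SMALL,
    heaped = FALSE, rounded = FALSE,
    missing_bw = FALSE, missing_ga = FALSE, missing_sex = FALSE,
    implausible_bw = FALSE, implausible_ga = FALSE, implausible_combo = FALSE
  )

  bw <- df$bw_grams
  ga <- df$ga_days
  sex <- df$sex

  # 1. Heaping: relocate a share of flank-window weights to exactly 2500 g.
  flank <- which(bw >= 2250 & bw <= 2750 & bw != 2500L)
  heap <- flank[stats::runif(length(flank)) < config$heaping_fraction]
  bw[heap] <- 2500L
  truth$heaped[heap] <- TRUE

  # 2. Digit preference: round a share of the remaining weights to 100 g.
  cand <- setdiff(seq_len(n), heap)
  rnd <- cand[stats::runif(length(cand)) < config$round100_fraction]
  bw[rnd] <- as.integer(round(bw[rnd] / 100) * 100)
  truth$rounded[rnd] <- TRUE

  # 3. Missingness (independent per variable, MCAR).
  mb <- stats::runif(n) < df$missing_bw_rate
  mg <- stats::runif(n) < df$missing_ga_rate
  ms <- stats::runif(n) < df$missing_sex_rate
  bw[mb] <- NA_integer_
  ga[mg] <- NA_integer_
  sex[ms] <- NA_character_
  truth$missing_bw <- mb
  truth$missing_ga <- mg
  truth$missing_sex <- ms

  # 4. Implausible injection, on records with the relevant field observed.
  pick <- function(eligible, rate) {
    k <- as.integer(round(rate * n))
    if (k == 0 || length(eligible) == 0) return(integer(0))
    eligible[sample.int(length(eligible), min(k, length(eligible)))]
  }
  taken <- integer(0)
  ib <- pick(setdiff(which(!mb), taken), config$implausible_bw_rate)
  bw[ib] <- ifelse(stats::runif(length(ib)) < 0.5,
                   sample(50:249, length(ib), replace = TRUE),
                   sample(6500:7999, length(ib), replace = TRUE))
  truth$implausible_bw[ib] <- TRUE
  taken <- c(taken, ib)
  ig <- pick(setdiff(which(!mg), taken), config$implausible_ga_rate)
  ga[ig] <- sample(c(100:153, 315:340), length(ig), replace = TRUE)
  truth$implausible_ga[ig] <- TRUE
  taken <- c(taken, ig)
  # Combination injection: in-window weight ~10 family SDs above the weekly
  # mean, far outside any plausible +/-5 SD envelope.
  ic <- pick(setdiff(which(!mb & !mg), taken), config$implausible_combo_rate)
  bw[ic] <- as.integer(pmin(6400, round(df$mu[ic] + 10 * df$sdv[ic])))
  truth$implausible_combo[ic] <- TRUE

  records <- tibble::tibble(
    record_id = df$record_id,
    country_code = df$country_code,
    year = df$year,
    ga_days = ga,
    ga_week_resolution = FALSE,
    bw_grams = bw,
    sex = sex,
    plurality = df$plurality
  )
  list(records = records, truth = truth, config = config)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Per-country target small/large composite prevalences of the packaged
# 23-country scenario. Smalls span 7.6-26% with median 11.7%; larges have
# median 18.1%. High-small countries get low-large targets and vice versa.
SCENARIO_SMALL_TARGETS <- c(
  7.6, 8.4, 9.0, 9.5, 9.9, 10.3, 10.8, 11.2, 11.4, 11.5, 11.6, 11.7,
  12.1, 12.6, 13.2, 14.2, 14.8, 15.4, 15.7, 16.4, 18.6, 22.0, 26.0) / 100
SCENARIO_LARGE_TARGETS <- rev(c(
  5.6, 8.2, 10.9, 11.9, 12.6, 13.8, 15.0, 16.5, 16.7, 17.4, 17.8, 18.1,
  19.3, 20.4, 21.0, 21.2, 22.1, 22.9, 23.5, 24.8, 25.9, 26.4, 28.8)) / 100

#' Packaged 23-country demonstration scenario
#'
#' A multi-country configuration for integration testing and demonstration:
#' 23 synthetic countries whose target small-composite prevalences span
#' 7.6% to 26% with median 11.7% and whose large-composite targets have
#' median 18.1% (targets are generator inputs, not claims about any real
#' country). Twenty countries contribute 10 years of data; three contribute
#' fewer than four years and therefore drop out of trend estimation. Mild
#' corruption (1–2% missingness, 5% heaping of the flank window, 2%
#' rounding, 0.2% implausible injections per category) keeps every country
#' above the 80% completeness bar. A four-region map is attached.
#'
#' Per-country rates derive from the composite targets: preterm is taken as
#' 45% of the small target, then `sga = (small - pt) / (1 - pt)` and
#' `lga = large / (1 - pt)`, since small = pt + (1 - pt) * sga and
#' large = (1 - pt) * lga under independence of the size z-score and
#' gestational age.
#'
#' @param births_per_country Total births per country (split across its
#'   years), default 50000.
#' @param seed Seed for [generate_registry()].
#' @return A [generator_config()] with attributes `region_map` (an
#'   [sdg_region_map()]) and `targets` (tibble of configured per-country
#'   rates).
#' @export
scenario_paperlike <- function(births_per_country = 50000, seed = 20260901) {
  codes <- sprintf("C%02d", 1:23)
  years_list <- c(rep(list(2010:2019), 20),
                  list(2018:2019), list(2016:2017), list(2017:2019))
  regions <- rep(c("Region A", "Region B", "Region C", "Region D"),
                 length.out = 23)
  specs <- vector("list", 23)
  targets <- vector("list", 23)
  for (i in 1:23) {
    small <- SCENARIO_SMALL_TARGETS[i]
    large <- SCENARIO_LARGE_TARGETS[i]
    pt <- 0.45 * small
    sga <- (small - pt) / (1 - pt)
    lga <- large / (1 - pt)
    yrs <- years_list[[i]]
    specs[[i]] <- country_spec(
      country_code = codes[i], years = yrs,
      births_per_year = max(1L, as.integer(round(births_per_country / length(yrs)))),
      preterm_rate = pt, sga_rate = sga, lga_rate = lga
    )
    targets[[i]] <- tibble::tibble(country_code = codes[i],
                                   target_small = small, target_large = large,
                                   preterm_rate = pt, sga_rate = sga,
                                   lga_rate = lga,
                                   n_years = length(yrs))
  }
  cfg <- generator_config(
    countries = specs,
    missing_bw = 0.01, missing_ga = 0.02, missing_sex = 0.005,
    heaping_fraction = 0.05, round100_fraction = 0.02,
    implausible_bw_rate = 0.002, implausible_ga_rate = 0.002,
    implausible_combo_rate = 0.002,
    seed = seed
  )
  attr(cfg, "region_map") <- sdg_region_map(codes, regions)
  attr(cfg, "targets") <- dplyr::bind_rows(targets)
  cfg
}
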