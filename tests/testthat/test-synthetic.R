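test_that("the same seed reproduces the registry exactly", {
  cfg <- function() generator_config(
    country_spec("AA", 2015:2016, 2000),
    missing_bw = 0.02, heaping_fraction = 0.1,
    implausible_bw_rate = 0.01, seed = 99)
  g1 <- generate_registry(cfg())
  g2 <- generate_registry(cfg())
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_registry(generator_config(
    country_spec("AA", 2015:2016, 2000), seed = 100))
  expect_false(identical(g1$records$bw_grams, g3$records$bw_grams))
})

test_that("zero corruption means the cascade removes nothing and truth matches pipeline", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015, 10000), seed = 101))
  out <- apply_exclusions(gen$records)
  expect_identical(nrow(out$excluded), 0L)
  typed <- classify_births(out$included, gen$config$standard)
  est <- mean(typed$small)
  truth <- mean(gen$truth$true_small)
  expect_identical(est, truth)
})

test_that("defect tags describe exactly the applied corruptions", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015, 20000),
    missing_bw = 0.05, missing_ga = 0.05, missing_sex = 0.02,
    heaping_fraction = 0.3, seed = 102))
  r <- gen$records
  t <- gen$truth
  expect_identical(is.na(r$bw_grams), t$missing_bw)
  expect_identical(is.na(r$ga_days), t$missing_ga)
  expect_identical(is.na(r$sex), t$missing_sex)
  heaped_bw <- r$bw_grams[t$heaped & !t$missing_bw]
  expect_true(all(heaped_bw == 2500L))
})

test_that("hard-limit injections are excluded with the intended reason", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015, 20000),
    implausible_bw_rate = 0.01, implausible_ga_rate = 0.01,
    implausible_combo_rate = 0.01, seed = 103))
  out <- apply_exclusions(gen$records)
  ex <- out$excluded
  t <- gen$truth
  bw_ids <- t$record_id[t$implausible_bw]
  ga_ids <- t$record_id[t$implausible_ga]
  expect_identical(sort(ex$record_id[ex$reason == "implausible_bw"]),
                   sort(bw_ids))
  expect_identical(sort(ex$record_id[ex$reason == "implausible_ga"]),
                   sort(ga_ids))
  # envelope-violating injections (>5 SD by construction) at >= 95%
  combo_ids <- t$record_id[t$implausible_combo]
  caught <- ex$record_id[ex$reason == "implausible_combo"]
  expect_gte(length(intersect(caught, combo_ids)) / length(combo_ids), 0.95)
})

test_that("toy standard knots follow the family's quantiles and location shifts", {
  g <- newborntypes::toy_growth_params(sex_offset_g = 50)
  std <- make_toy_standard(growth = g)
  m <- std[std$sex == "male", ]
  f <- std[std$sex == "female", ]
  expect_equal(m$p10_g, f$p10_g + 50)
  expect_equal(m$p90_g, f$p90_g + 50)
  # increasing mean in gestational age -> strictly increasing p10 knots
  expect_true(all(diff(f$p10_g) > 0))
  bad <- newborntypes::toy_growth_params()
  bad$sd_fun <- function(ga) rep(-1, length(ga))
  expect_error(make_toy_standard(growth = bad), "scale")
})

test_that("SGA and LGA calibrate to the configured targets", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015, 50000, sga_rate = 0.10, lga_rate = 0.10),
    seed = 104))
  typed <- classify_births(gen$records, gen$config$standard)
  se <- sqrt(0.1 * 0.9 / 50000)
  expect_lt(abs(mean(typed$size_class == "SGA") - 0.10), 3 * se)
  expect_lt(abs(mean(typed$size_class == "LGA") - 0.10), 3 * se)
  # asymmetric targets
  gen2 <- generate_registry(generator_config(
    country_spec("AA", 2015, 50000, sga_rate = 0.17, lga_rate = 0.06),
    seed = 105))
  typed2 <- classify_births(gen2$records, gen2$config$standard)
  expect_lt(abs(mean(typed2$size_class == "SGA") - 0.17),
            3 * sqrt(0.17 * 0.83 / 50000))
  expect_lt(abs(mean(typed2$size_class == "LGA") - 0.06),
            3 * sqrt(0.06 * 0.94 / 50000))
})

test_that("infeasible SGA/LGA targets are rejected before sampling", {
  expect_error(country_spec("AA", 2015, 100, sga_rate = 0.6, lga_rate = 0.5),
               "infeasible")
  expect_error(generator_config(country_spec("AA", 2015, 100),
                                heaping_fraction = 1.2, seed = 1),
               "rates")
  expect_error(generator_config(country_spec("AA", 2015, 100)), "seed")
})

test_that("the packaged scenario has 23 countries, spanning targets, passing completeness", {
  cfg <- scenario_paperlike(births_per_country = 1000, seed = 1)
  expect_length(cfg$countries, 23)
  tg <- attr(cfg, "targets")
  expect_equal(median(tg$target_small), 0.117)
  expect_equal(median(tg$target_large), 0.181)
  expect_equal(range(tg$target_small), c(0.076, 0.26))
  expect_identical(sum(tg$n_years < 4), 3L)
  map <- attr(cfg, "region_map")
  expect_identical(sort(unique(map$region)),
                   c("Region A", "Region B", "Region C", "Region D"))
  # completeness stays far above the 80% inclusion bar by construction
  gen <- generate_registry(cfg)
  cm <- completeness(gen$records)
  expect_true(all(cm$pct_missing < 20))
  chk <- inclusion_check(95, 95, setNames(100 - cm$pct_missing, cm$variable))
  expect_true(chk$pass)
})
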