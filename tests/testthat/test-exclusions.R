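test_that("envelope mean/SD/bounds match hand arithmetic", {
  recs <- births(ga_days = 280L, bw_grams = c(3000L, 3200L, 3400L))
  env <- build_envelope(recs, multiplier = 5, min_cell = 2)
  expect_identical(env$ga_week, 40L)
  expect_equal(env$mean_bw, 3200)
  expect_equal(env$sd_bw, 200)   # sample (n - 1) SD
  expect_equal(env$lower, 2200)
  expect_equal(env$upper, 4200)
})

test_that("sparse weekly cells yield undefined envelope bounds", {
  recs <- births(ga_days = c(280L, 196L), bw_grams = c(3200L, 900L))
  env <- build_envelope(recs, min_cell = 2)
  expect_true(all(is.na(env$lower)))
  expect_identical(build_envelope(births()[0, ], min_cell = 2)$ga_week,
                   integer(0))
})

test_that("envelope bounds on generated data always bracket the mean", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015, 20000), seed = 11))
  env <- build_envelope(gen$records, multiplier = 5, min_cell = 10)
  defined <- !is.na(env$lower)
  expect_true(any(defined))
  expect_true(all(env$lower[defined] < env$mean_bw[defined]))
  expect_true(all(env$mean_bw[defined] < env$upper[defined]))
})

test_that("cascade attributes single reasons in the documented order", {
  recs <- dplyr::bind_rows(
    births(ga_days = NA, bw_grams = 3000L),          # missing_ga
    births(ga_days = 280L, bw_grams = NA),           # missing_bw
    births(ga_days = NA, bw_grams = NA),             # missing_both
    births(ga_days = NA, bw_grams = NA, sex = NA),   # still missing_both
    births(sex = NA_character_),                     # missing_sex
    births(ga_days = NA, bw_grams = 3000L, sex = NA),# missing_ga precedence
    births(bw_grams = 200L),                         # implausible_bw (<250)
    births(bw_grams = 6500L),                        # implausible_bw (>=6500)
    births(ga_days = 153L, bw_grams = 450L),         # implausible_ga (21+6)
    births(ga_days = 315L),                          # implausible_ga (45+0)
    births()                                         # clean
  )
  out <- apply_exclusions(recs)
  expect_identical(out$excluded$reason,
                   c("missing_ga", "missing_bw", "missing_both",
                     "missing_both", "missing_sex", "missing_ga",
                     "implausible_bw", "implausible_bw",
                     "implausible_ga", "implausible_ga"))
  expect_identical(nrow(out$included), 1L)
})

test_that("boundary values of the hard limits are read literally", {
  recs <- dplyr::bind_rows(
    births(bw_grams = 249L), births(bw_grams = 250L),
    births(bw_grams = 6499L), births(bw_grams = 6500L),
    births(ga_days = 154L, bw_grams = 700L),
    births(ga_days = 314L, bw_grams = 3400L)
  )
  out <- apply_exclusions(recs)
  # 250 g and 6499 g plausible; 249 g and 6500 g implausible;
  # 154 and 314 days inside the window
  expect_identical(sum(out$excluded$reason == "implausible_bw"), 2L)
  expect_identical(out$excluded$bw_grams, c(249L, 6500L))
  expect_identical(nrow(out$included), 4L)
})

test_that("combination exclusions use the envelope built from survivors", {
  set.seed(7)
  base <- births(ga_days = 280L, bw_grams = as.integer(rnorm(200, 3300, 150)))
  outlier <- births(ga_days = 280L, bw_grams = 5500L)  # > mean + 5 SD, in hard limits
  out <- apply_exclusions(dplyr::bind_rows(base, outlier))
  expect_identical(out$excluded$reason, "implausible_combo")
  expect_identical(out$excluded$bw_grams, 5500L)
})

test_that("flow conservation holds exactly and cascade is idempotent", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015:2016, 5000),
    missing_bw = 0.05, missing_ga = 0.05, missing_sex = 0.02,
    implausible_bw_rate = 0.01, implausible_ga_rate = 0.01,
    implausible_combo_rate = 0.01, seed = 5))
  out <- apply_exclusions(gen$records)
  expect_identical(out$flow$n_input,
                   out$flow$n_included + sum(out$flow$exclusions$n))
  expect_identical(nrow(out$included) + nrow(out$excluded),
                   nrow(gen$records))
  # re-running on the included set with the envelope held fixed excludes nothing
  again <- apply_exclusions(out$included, envelope = out$envelope)
  expect_identical(nrow(again$excluded), 0L)
  expect_identical(nrow(again$included), nrow(out$included))
})

test_that("the included set does not depend on missing/implausible rule order", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015, 4000),
    missing_bw = 0.1, missing_ga = 0.1, missing_sex = 0.05,
    implausible_bw_rate = 0.02, implausible_ga_rate = 0.02, seed = 9))
  recs <- gen$records
  out <- apply_exclusions(recs)
  # independent formulation: rules 1-6 are order-invariant filters
  lim <- plausibility_limits()
  pass16 <- !is.na(recs$ga_days) & !is.na(recs$bw_grams) & !is.na(recs$sex) &
    recs$bw_grams >= lim$bw_min_g & recs$bw_grams < lim$bw_max_g &
    recs$ga_days >= lim$ga_min_days & recs$ga_days <= lim$ga_max_days
  env <- build_envelope(recs[pass16, ], multiplier = lim$combo_sd_multiplier,
                        min_cell = lim$min_cell)
  idx <- match(recs$ga_days %/% 7L, env$ga_week)
  in_env <- is.na(env$lower[idx]) |
    (recs$bw_grams >= env$lower[idx] & recs$bw_grams <= env$upper[idx])
  expect_identical(out$included$record_id,
                   recs$record_id[pass16 & (is.na(in_env) | in_env)])
})

test_that("flow_summary reports one-decimal percentages of input", {
  flow <- flow_accounting(1000, c(missing_ga = 16, missing_bw = 9))
  fs <- flow_summary(flow)
  expect_identical(fs$n[fs$reason == "final_dataset"], 975)
  expect_equal(fs$pct_of_input[fs$reason == "missing_ga"], 1.6)
  expect_equal(fs$pct_of_input[fs$reason == "total_excluded"], 2.5)
  # zero exclusions
  fs0 <- flow_summary(flow_accounting(500, c(missing_ga = 0)))
  expect_equal(fs0$pct_of_input[fs0$reason == "total_excluded"], 0)
  expect_identical(fs0$n[fs0$reason == "final_dataset"], 500)
  expect_error(flow_summary(flow_accounting(0, c(missing_ga = 0))), "zero")
  expect_error(flow_accounting(10, c(missing_ga = 4), n_included = 5))
})
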