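test_that("heaping index follows its definition, including edge cases", {
  bw <- c(rep(2500L, 10), rep(2400L, 40), rep(2600L, 50))
  expect_equal(heaping_index(bw), 10 / 90)
  # no mass at exactly 2500, non-empty flanks -> 0
  expect_equal(heaping_index(c(2400L, 2600L)), 0)
  # all mass at 2500, empty flanks -> undefined, not zero
  expect_true(is.na(heaping_index(rep(2500L, 5))))
  # flank boundaries: 2249 and 2751 are outside, 2250 and 2750 inside
  expect_equal(heaping_index(c(2500L, 2250L, 2750L)), 1 / 2)
  expect_true(is.na(heaping_index(c(2500L, 2249L, 2751L))))
})

test_that("heaping index ignores records outside the 2250-2750 window", {
  base <- c(rep(2500L, 5), rep(2300L, 20), rep(2700L, 25))
  with_noise <- c(base, rep(500L, 100), rep(4000L, 200), rep(2249L, 30))
  expect_equal(heaping_index(with_noise), heaping_index(base))
})

test_that("heaping index rises strictly with the injected heaping fraction", {
  fractions <- c(0, 0.2, 0.5, 0.9)
  idx <- vapply(fractions, function(f) {
    gen <- generate_registry(generator_config(
      country_spec("AA", 2015, 20000), heaping_fraction = f, seed = 303))
    heaping_index(gen$records$bw_grams)
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("tail proportions use strict < for weight and inclusive <= 28+6 weeks", {
  recs <- births(bw_grams = c(400L, 900L, 3000L), ga_days = c(280L, 280L, 280L))
  tp <- tail_proportions(recs)
  expect_equal(tp$pct_bw_lt_500, 100 / 3)
  expect_equal(tp$pct_bw_lt_1000, 200 / 3)
  # boundary: exactly 500 g does not count toward <500
  expect_equal(tail_proportions(births(bw_grams = 500L))$pct_bw_lt_500, 0)
  # 202 days (28+6) inclusive, 203 (29+0) not
  tp2 <- tail_proportions(births(ga_days = c(202L, 203L)))
  expect_equal(tp2$pct_ga_le_28w6d, 50)
})

test_that("tail proportions are monotone non-decreasing in the threshold", {
  set.seed(21)
  bw <- as.integer(runif(500, 300, 4500))
  recs <- births(bw_grams = bw)
  n <- length(bw)
  shares <- vapply(c(500, 1000, 2000, 4000),
                   function(th) sum(bw < th) / n, numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_equal(tail_proportions(recs)$pct_bw_lt_500, 100 * shares[1])
})

test_that("completeness measures pre-exclusion missingness per variable", {
  recs <- dplyr::bind_rows(births(bw_grams = c(NA, NA)), births()[rep(1, 98), ])
  cm <- completeness(recs)
  expect_equal(cm$pct_missing[cm$variable == "bw"], 2)
  expect_equal(cm$pct_missing[cm$variable == "ga"], 0)
  expect_error(completeness(births()[0, ]), "no records")
})

test_that("injected missingness is recovered within binomial error", {
  gen <- generate_registry(generator_config(
    country_spec("AA", 2015, 40000), missing_bw = 0.05, seed = 77))
  cm <- completeness(gen$records)
  p_hat <- cm$pct_missing[cm$variable == "bw"] / 100
  se <- sqrt(0.05 * 0.95 / 40000)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("inclusion check needs 80% on coverage, facility births and completeness", {
  ok <- inclusion_check(85, 90, c(bw = 95, ga = 92, sex = 99))
  expect_true(ok$pass)
  bad_bw <- inclusion_check(85, 90, c(bw = 79, ga = 92, sex = 99))
  expect_false(bad_bw$pass)
  expect_identical(bad_bw$reasons, "bw_completeness")
  bad_cov <- inclusion_check(79, 90, c(bw = 100, ga = 100, sex = 100))
  expect_identical(bad_cov$reasons, "coverage")
  # missing metadata is a fail, not a pass
  expect_identical(inclusion_check(NA, 90, c(bw = 95, ga = 92, sex = 99))$reasons,
                   "insufficient metadata")
  expect_identical(inclusion_check(85, 90, c(bw = 95, ga = 92))$reasons,
                   "insufficient metadata")
})

test_that("sensitivity filter flags strictly more than 20% missingness", {
  qt <- tibble::tibble(country_code = c("AA", "BB", "CC"),
                       year = 2015L,
                       pct_missing_bw = c(5, 20, 5),
                       pct_missing_ga = c(21, 20, 20),
                       pct_missing_sex = c(0, 0, 0))
  out <- sensitivity_filter(qt)
  expect_identical(out$flagged, c(TRUE, FALSE, FALSE))
})

test_that("sensitivity filter finds exactly the injected high-missingness countries", {
  specs <- c(
    lapply(sprintf("C%02d", 1:8), function(cc)
      country_spec(cc, 2015, 2000)),
    list(country_spec("H1", 2015, 2000, missing_ga = 0.35),
         country_spec("H2", 2015, 2000, missing_bw = 0.30))
  )
  gen <- generate_registry(generator_config(specs, missing_ga = 0.02, seed = 13))
  qr <- quality_report(gen$records)
  out <- sensitivity_filter(qr)
  expect_identical(sort(out$country_code[out$flagged]), c("H1", "H2"))
})

test_that("quality report splits denominators: missingness pre-, tails post-exclusion", {
  recs <- dplyr::bind_rows(
    births(bw_grams = NA)[rep(1, 10), ],                   # excluded, missing_bw
    births(bw_grams = 400L, ga_days = 200L)[rep(1, 5), ],  # tiny preterm, kept
    births()[rep(1, 85), ]
  )
  qr <- quality_report(recs)
  expect_equal(qr$n_total, 100L)
  expect_equal(qr$pct_missing_bw, 10)
  expect_equal(qr$n_included, 90L)
  expect_equal(qr$pct_bw_lt_500, 100 * 5 / 90)
  expect_equal(qr$pct_ga_le_28w6d, 100 * 5 / 90)
})
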