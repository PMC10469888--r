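cfg <- cfg_default

test_that("incidence counts first-ever use and honours the one-year lookback", {
  persons <- person_row()
  # only-ever record: incident in its month
  d <- drug_rows("2015-06-10")
  inc <- monthly_incidence(d, persons, cfg)
  m <- month_index(as.Date("2015-06-10"), cfg$study_start)
  expect_identical(inc$numerator[inc$month == m], 1L)
  # prior record 6 months earlier: lookback hit, not incident
  d2 <- drug_rows(c("2014-12-10", "2015-06-10"))
  inc2 <- monthly_incidence(d2, persons, cfg)
  expect_identical(inc2$numerator[inc2$month == m], 0L)
  # but the December record itself is incident
  m2 <- month_index(as.Date("2014-12-10"), cfg$study_start)
  expect_identical(inc2$numerator[inc2$month == m2], 1L)
})

test_that("persons without a full lookback of observation are not evaluable", {
  p <- person_row(obs_start = "2015-01-01")
  inc <- monthly_incidence(drug_rows("2015-06-10"), p, cfg)
  # month 66 is 2015-07: person has < 365 days of observation before it
  expect_identical(inc$denominator[inc$month ==
    month_index(as.Date("2015-06-01"), cfg$study_start)], 0)
  expect_true(is.na(inc$value[inc$month ==
    month_index(as.Date("2015-06-01"), cfg$study_start)]))
  first_ok <- month_index(as.Date("2016-01-01"), cfg$study_start)
  expect_identical(inc$denominator[inc$month == first_ok], 1)
})

test_that("an episode spanning three months is prevalent in all three", {
  persons <- person_row()
  eps <- data.frame(person_id = "p1", drug_class = "isotretinoin",
                    start = as.Date("2015-06-10"), end = as.Date("2015-08-05"),
                    n_records = 2L, last_record_date = as.Date("2015-07-07"))
  pr <- monthly_prevalence(eps, persons, cfg)
  m <- month_index(as.Date("2015-06-01"), cfg$study_start)
  expect_identical(pr$numerator[pr$month %in% (m + 0:2)], rep(1L, 3))
  expect_identical(sum(pr$numerator), 3L)
  # no users: all-zero numerators, zero values where defined
  pr0 <- monthly_prevalence(eps[0, ], persons, cfg)
  expect_true(all(pr0$numerator == 0L))
  expect_true(all(pr0$value[!is.na(pr0$value)] == 0))
})

test_that("incident users are prevalent the same month on simulated cohorts", {
  sim <- simulate_cdm(busy_scenario(71, n = 300), cfg)
  inc <- monthly_incidence(sim$drugs, sim$persons, cfg)
  eps <- build_all_episodes(sim$drugs, cfg)
  prev <- monthly_prevalence(eps, sim$persons, cfg)
  expect_true(all(prev$numerator >= inc$numerator))
  expect_true(all(inc$value[!is.na(inc$value)] >= 0))
  expect_true(all(prev$value[!is.na(prev$value)] >= 0))
})

test_that("age-band denominators sum to the overall denominator each month", {
  sim <- simulate_cdm(busy_scenario(72, n = 400), cfg)
  overall <- population_by_month(sim$persons, cfg)
  bands <- population_by_month(sim$persons, cfg, by_age_band = TRUE)
  summed <- tapply(bands$denominator, bands$month, sum)
  expect_identical(as.integer(summed), as.integer(overall$denominator))
})

test_that("discontinuation proportion divides by previous-quarter users", {
  # 100 users active in Q2 2015; 5 discontinue in July 2015
  eps <- data.frame(
    person_id = sprintf("u%03d", 1:100), drug_class = "isotretinoin",
    start = as.Date("2015-04-10"), end = as.Date("2015-06-20"),
    n_records = 2L, last_record_date = as.Date("2015-05-22"),
    assessable = TRUE, discontinued = c(rep(TRUE, 5), rep(FALSE, 95)),
    discontinuation_date = as.Date(c(rep("2015-07-05", 5), rep(NA, 95))))
  # place the discontinuation date in July for the five
  eps$end[1:5] <- as.Date("2015-07-05")
  dr <- discontinuation_rate(eps, cfg)
  m <- month_index(as.Date("2015-07-01"), cfg$study_start)
  row <- dr[dr$month == m, ]
  expect_identical(row$numerator, 5L)
  expect_identical(row$denominator, 100L)
  expect_equal(row$value, 0.05)
  # month following a user-free quarter is undefined
  expect_true(is.na(dr$value[dr$month == 0]))
})

test_that("contraception series split coverage at start from start within 90 days", {
  ret <- data.frame(person_id = c("p1", "p2", "p3"),
                    drug_class = "isotretinoin",
                    start = as.Date("2015-06-10"), end = as.Date("2015-07-09"),
                    n_records = 1L, last_record_date = as.Date("2015-06-10"))
  contra <- data.frame(person_id = c("p1", "p2"),
                       drug_class = c("contraceptive_user_independent",
                                      "contraceptive_hormonal"),
                       start = as.Date(c("2014-03-01", "2015-05-11")),
                       end = as.Date(c("2017-02-28", "2015-08-01")),
                       n_records = 1L,
                       last_record_date = as.Date(c("2014-03-01", "2015-05-11")))
  cov <- contraception_coverage(contra, cfg)
  cs <- contraception_proportions(ret, cov, contra, cfg)
  m <- month_index(as.Date("2015-06-01"), cfg$study_start)
  a <- cs[cs$series_name == "contraception_covered" & cs$month == m, ]
  b <- cs[cs$series_name == "contraception_prior90" & cs$month == m, ]
  expect_equal(a$value, 1 / 3)   # p1 inside device coverage
  expect_equal(b$value, 1 / 3)   # only p2 started contraception within 90 d
  # empty coverage: series A identically zero
  cs0 <- contraception_proportions(ret, cov[0, ], contra[0, ], cfg)
  expect_true(all(cs0$value[!is.na(cs0$value)] == 0))
})

test_that("pregnancy-testing compliance uses the +/-90-day window", {
  persons <- person_row()
  ret <- data.frame(person_id = "p1", drug_class = "isotretinoin",
                    start = as.Date("2015-06-10"), end = as.Date("2015-07-09"),
                    n_records = 1L, last_record_date = as.Date("2015-06-10"))
  ev <- function(date) data.frame(person_id = "p1", event_date = as.Date(date),
                                  event_kind = "pregnancy_test", event_code = "PT")
  m <- month_index(as.Date("2015-06-01"), cfg$study_start)
  ok <- pregnancy_testing_proportions(ev("2015-05-31"), ret, persons, cfg)
  expect_equal(ok$value[ok$series_name == "pregtest_around_start" &
                          ok$month == m], 1)
  far <- pregnancy_testing_proportions(ev("2015-02-01"), ret, persons, cfg)
  expect_equal(far$value[far$series_name == "pregtest_around_start" &
                           far$month == m], 0)
})

test_that("series are non-negative, bounded where proportions, masked on export only", {
  sim <- simulate_cdm(busy_scenario(73, n = 300), cfg)
  eps <- build_all_episodes(sim$drugs, cfg)
  eps <- flag_discontinuation(eps, sim$drugs, sim$persons, cfg)
  reps <- eps[eps$drug_class %in% names(cfg$retinoid_atc), ]
  cov <- contraception_coverage(
    eps[startsWith(eps$drug_class, "contraceptive"), ], cfg)
  cs <- contraception_proportions(reps, cov,
    eps[startsWith(eps$drug_class, "contraceptive"), ], cfg)
  pv <- cs$value[!is.na(cs$value)]
  expect_true(all(pv >= 0 & pv <= 1))
  # the quarterly-denominator discontinuation measure is non-negative (it can
  # exceed 1 when a month's discontinuers were not prior-quarter users)
  dr <- discontinuation_rate(reps, cfg)
  vals <- dr$value[!is.na(dr$value)]
  expect_true(all(vals >= 0))
  masked <- mask_small_cells(dr, cfg)
  small <- masked$numerator > 0 & masked$numerator < cfg$small_cell_threshold
  expect_true(all(masked$numerator_display[small] == "<5"))
  expect_identical(masked$numerator, dr$numerator)   # values stay exact
})
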