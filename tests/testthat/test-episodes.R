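cfg <- cfg_default

test_that("a single record becomes one supply-length episode", {
  eps <- build_episodes(drug_rows("2015-01-01"), cfg)
  expect_identical(nrow(eps), 1L)
  expect_identical(eps$start, as.Date("2015-01-01"))
  expect_identical(eps$end, as.Date("2015-01-30"))
})

test_that("a sub-30-day coverage gap merges; a 30+ day gap splits", {
  # gap 2015-01-31..2015-02-19 is 20 days < 30: merged, exposed throughout
  eps <- build_episodes(drug_rows(c("2015-01-01", "2015-02-20")), cfg)
  expect_identical(nrow(eps), 1L)
  expect_identical(eps$end, as.Date("2015-03-21"))
  expect_identical(eps$n_records, 2L)
  # gap of 60 days >= 30: two episodes
  eps2 <- build_episodes(drug_rows(c("2015-01-01", "2015-04-01")), cfg)
  expect_identical(nrow(eps2), 2L)
  # boundary: gap of exactly 30 days splits (merge iff gap < 30)
  eps3 <- build_episodes(drug_rows(c("2015-01-01", "2015-03-02")), cfg)
  expect_identical(nrow(eps3), 2L)
  eps4 <- build_episodes(drug_rows(c("2015-01-01", "2015-03-01")), cfg)
  expect_identical(nrow(eps4), 1L)
})

test_that("unsorted or multi-person input is refused; empty input is empty", {
  expect_error(build_episodes(drug_rows(c("2015-02-01", "2015-01-01")), cfg),
               "sorted")
  two <- rbind(drug_rows("2015-01-01"), drug_rows("2015-01-05", person = "p2"))
  expect_error(build_episodes(two, cfg), "single person")
  expect_identical(nrow(build_episodes(drug_rows(character(0)), cfg)), 0L)
})

test_that("missing days_supply falls back to the 30-day programme default", {
  d <- drug_rows("2015-01-01")
  d$days_supply <- NA_integer_
  eps <- build_episodes(d, cfg)
  expect_identical(eps$end, as.Date("2015-01-30"))
})

test_that("episodes within a person and class never overlap and keep the gap", {
  sim <- simulate_cdm(busy_scenario(31, n = 300), cfg)
  eps <- build_all_episodes(sim$drugs, cfg)
  for (g in split(eps, paste(eps$person_id, eps$drug_class))) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      gaps <- as.numeric(g$start[-1] - g$end[-nrow(g)]) - 1
      expect_true(all(gaps >= cfg$episode_gap_days))
    }
  }
})

test_that("discontinuation needs 90 record-free days and an assessable window", {
  persons <- person_row()
  # next record 61 days after the last: not discontinued
  d <- drug_rows(c("2015-03-01", "2015-05-01"))
  eps <- flag_discontinuation(build_episodes(d, cfg), d, persons, cfg)
  expect_identical(nrow(eps), 2L)
  expect_false(eps$discontinued[1])
  expect_true(eps$discontinued[2])
  expect_identical(eps$discontinuation_date[2], eps$end[2])
  # no further record, window inside observation: discontinued at episode end
  d2 <- drug_rows("2015-03-01")
  eps2 <- flag_discontinuation(build_episodes(d2, cfg), d2,
                               person_row(obs_end = "2016-01-01"), cfg)
  expect_true(eps2$assessable)
  expect_true(eps2$discontinued)
  # window truncated by the study end: not assessable
  d3 <- drug_rows("2020-11-15")
  eps3 <- flag_discontinuation(build_episodes(d3, cfg), d3, persons, cfg)
  expect_false(eps3$assessable)
  expect_false(eps3$discontinued)
})

test_that("a 30-day sensitivity gap never yields fewer discontinuations", {
  cfg30 <- study_config(discontinuation_gap_days = 30)
  for (seed in c(41, 42)) {
    sim <- simulate_cdm(busy_scenario(seed, n = 250), cfg)
    eps <- build_all_episodes(sim$drugs, cfg)
    n90 <- sum(flag_discontinuation(eps, sim$drugs, sim$persons, cfg)$discontinued)
    n30 <- sum(flag_discontinuation(eps, sim$drugs, sim$persons, cfg30)$discontinued)
    expect_gte(n30, n90)
  }
  # crafted: next record 60 days after the last (episode-breaking 30-day
  # coverage gap) discontinues only under the 30-day rule
  persons <- person_row()
  d <- drug_rows(c("2015-03-01", "2015-04-30"))
  eps <- build_all_episodes(d, cfg)
  expect_identical(nrow(eps), 2L)
  expect_false(flag_discontinuation(eps, d, persons, cfg)$discontinued[1])
  expect_true(flag_discontinuation(eps, d, persons, cfg30)$discontinued[1])
})

disc_episode <- function(class = "isotretinoin", end = "2016-05-01") {
  data.frame(person_id = "p1", drug_class = class,
             start = as.Date(end) - 60, end = as.Date(end), n_records = 2L,
             last_record_date = as.Date(end) - 29, assessable = TRUE,
             discontinued = TRUE, discontinuation_date = as.Date(end))
}
no_events <- data.frame(person_id = character(), event_date = as.Date(character()),
                        event_kind = character(), event_code = character())
no_pregs <- data.frame(person_id = character(), start = as.Date(character()),
                       end = as.Date(character()), colour = character())

test_that("folic acid within 90 days marks pregnancy wish for iso/alitretinoin only", {
  folic <- drug_rows("2016-06-15", atc = "B03BB01")
  out <- classify_discontinuation(disc_episode("isotretinoin"), no_events,
                                  folic, no_pregs, cfg)
  expect_identical(out$reason, "pregnancy_wish")
  out2 <- classify_discontinuation(disc_episode("acitretin"), no_events,
                                   folic, no_pregs, cfg)
  expect_identical(out2$reason, "unknown")
})

test_that("pregnancy outranks folic acid which outranks the ADR proxy", {
  folic <- drug_rows("2016-06-15", atc = "B03BB01")
  antidep <- drug_rows("2016-06-01", atc = "N06AB06")
  preg <- data.frame(person_id = "p1", start = as.Date("2016-07-01"),
                     end = as.Date("2017-03-30"), colour = "green")
  both <- rbind(folic, antidep)
  expect_identical(
    classify_discontinuation(disc_episode(), no_events, both, preg, cfg)$reason,
    "pregnancy")
  expect_identical(
    classify_discontinuation(disc_episode(), no_events, both, no_pregs, cfg)$reason,
    "pregnancy_wish")
  adr_ev <- data.frame(person_id = "p1", event_date = as.Date("2016-06-01"),
                       event_kind = "adr_diagnosis", event_code = "ADR_RETINOID")
  expect_identical(
    classify_discontinuation(disc_episode("acitretin"), adr_ev,
                             drug_rows(character(0)), no_pregs, cfg)$reason,
    "adr")
  # nothing in the window: the default reason is unknown
  expect_identical(
    classify_discontinuation(disc_episode(), no_events,
                             drug_rows(character(0)), no_pregs, cfg)$reason,
    "unknown")
})

test_that("with all reason probabilities zero every discontinuation is unknown", {
  sim <- simulate_cdm(busy_scenario(5, n = 250, adr_prob = 0, folic_prob = 0,
                                    pregtest_prob = 0, pregnancy_rate = 0), cfg)
  eps <- build_all_episodes(sim$drugs, cfg)
  eps <- flag_discontinuation(eps, sim$drugs, sim$persons, cfg)
  eps <- eps[eps$drug_class %in% names(cfg$retinoid_atc), ]
  out <- classify_discontinuation(eps, sim$events, sim$drugs, no_pregs, cfg)
  expect_gt(sum(out$discontinued), 0)
  expect_true(all(out$reason[out$discontinued] == "unknown"))
})

test_that("contraception coverage uses device episodes; hormonal only if permissive", {
  iud <- data.frame(person_id = "p1",
                    drug_class = "contraceptive_user_independent",
                    start = as.Date("2014-03-01"),
                    end = as.Date("2014-03-01") + 1094, n_records = 1L,
                    last_record_date = as.Date("2014-03-01"))
  horm <- data.frame(person_id = "p2", drug_class = "contraceptive_hormonal",
                     start = as.Date("2014-03-01"), end = as.Date("2014-06-01"),
                     n_records = 3L, last_record_date = as.Date("2014-05-01"))
  cov <- contraception_coverage(rbind(iud, horm), cfg)
  expect_identical(cov$person_id, "p1")
  expect_identical(as.numeric(cov$end - cov$start) + 1, 1095)
  permissive <- study_config(include_hormonal_coverage = TRUE)
  cov2 <- contraception_coverage(rbind(iud, horm), permissive)
  expect_setequal(cov2$person_id, c("p1", "p2"))
  expect_identical(nrow(contraception_coverage(iud[0, ], cfg)), 0L)
})
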