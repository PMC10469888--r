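cfg <- cfg_default

test_that("colour follows the recorded/imputed status of start and end", {
  # both recorded -> green, recorded dates kept
  g <- reconcile_pregnancies(
    preg_source_row(record_date = "2016-10-05",
                    recorded_start = "2016-01-10", recorded_end = "2016-10-05"),
    cfg)
  expect_identical(g$colour, "green")
  expect_identical(g$start, as.Date("2016-01-10"))
  expect_identical(g$end, as.Date("2016-10-05"))
  # end only -> yellow, start = end - 273
  y <- reconcile_pregnancies(
    preg_source_row(stream = "admin_diagnosis", record_date = "2016-10-05",
                    recorded_end = "2016-10-05"), cfg)
  expect_identical(y$colour, "yellow")
  expect_identical(y$start, as.Date("2016-01-06"))
  expect_identical(as.numeric(y$end - y$start), 273)
  # start only -> blue, end = start + 273
  b <- reconcile_pregnancies(
    preg_source_row(stream = "admin_diagnosis", record_date = "2016-03-01",
                    recorded_start = "2016-01-10"), cfg)
  expect_identical(b$colour, "blue")
  expect_identical(as.numeric(b$end - b$start), 273)
  # neither -> red, anchored on the record date
  r <- reconcile_pregnancies(
    preg_source_row(stream = "tailored", record_date = "2016-06-01"), cfg)
  expect_identical(r$colour, "red")
  expect_identical(as.numeric(r$end - r$start), 273)
})

test_that("a recorded gestational age replaces the 273-day imputation", {
  y <- reconcile_pregnancies(
    preg_source_row(record_date = "2016-10-05", recorded_end = "2016-10-05",
                    gest = 200L), cfg)
  expect_identical(y$start, as.Date("2016-10-05") - 200)
})

test_that("records of one pregnancy cluster; the registry stream wins", {
  recs <- rbind(
    preg_source_row(stream = "admin_diagnosis", record_date = "2016-10-01",
                    recorded_end = "2016-09-28"),
    preg_source_row(stream = "birth_registry", record_date = "2016-10-03",
                    recorded_start = "2016-01-10", recorded_end = "2016-10-05"),
    preg_source_row(stream = "tailored", record_date = "2016-08-15"))
  ev <- reconcile_pregnancies(recs, cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$colour, "green")
  expect_identical(ev$end, as.Date("2016-10-05"))   # registry over admin
  expect_identical(ev$source_streams, "admin_diagnosis,birth_registry,tailored")
  # a second pregnancy two years later stays separate
  recs2 <- rbind(recs,
                 preg_source_row(stream = "birth_registry",
                                 record_date = "2018-11-02",
                                 recorded_start = "2018-02-01",
                                 recorded_end = "2018-11-01"))
  expect_identical(nrow(reconcile_pregnancies(recs2, cfg)), 2L)
})

test_that("colour filtering keeps the requested certainty levels in order", {
  ev <- data.frame(person_id = c("a", "b", "c"),
                   start = as.Date("2016-01-01") + 0:2,
                   end = as.Date("2016-10-01") + 0:2,
                   colour = c("green", "yellow", "red"))
  expect_identical(filter_by_colour(ev)$person_id, c("a", "b"))
  expect_identical(filter_by_colour(ev, c("green", "yellow", "red"))$person_id,
                   c("a", "b", "c"))
  expect_identical(nrow(filter_by_colour(ev[0, ])), 0L)
})

test_that("overlap uses the 30-day teratogenic extension and pregnancy windows", {
  ep <- data.frame(person_id = "p1", drug_class = "isotretinoin",
                   start = as.Date("2016-01-01"), end = as.Date("2016-03-01"),
                   n_records = 3L, last_record_date = as.Date("2016-02-01"))
  no_drugs <- drug_rows(character(0))
  preg <- function(s, e = as.Date(s) + 273)
    data.frame(person_id = "p1", start = as.Date(s), end = as.Date(e),
               colour = "green")
  # starts 19 days after the episode end: exposed via the extension
  hit <- detect_overlap(preg("2016-03-20"), ep, no_drugs, cfg)
  expect_identical(hit$overlap_kind, "pregnancy_started_during_treatment")
  # 61 days after: outside the extension
  expect_identical(nrow(detect_overlap(preg("2016-05-01"), ep, no_drugs, cfg)), 0L)
  # retinoid record dated inside the pregnancy window
  d <- drug_rows("2016-04-15")
  hit2 <- detect_overlap(preg("2016-02-01", "2016-11-01"), ep[0, ], d, cfg)
  expect_identical(hit2$overlap_kind, "retinoid_started_during_pregnancy")
  expect_identical(hit2$overlap_date, as.Date("2016-04-15"))
})

test_that("each pregnancy contributes at most one case per overlap kind", {
  ep <- rbind(
    data.frame(person_id = "p1", drug_class = "isotretinoin",
               start = as.Date("2016-01-01"), end = as.Date("2016-03-01"),
               n_records = 1L, last_record_date = as.Date("2016-01-01")),
    data.frame(person_id = "p1", drug_class = "acitretin",
               start = as.Date("2016-02-01"), end = as.Date("2016-04-01"),
               n_records = 1L, last_record_date = as.Date("2016-02-01")))
  d <- drug_rows(c("2016-04-15", "2016-06-15"))
  preg <- data.frame(person_id = "p1", start = as.Date("2016-02-20"),
                     end = as.Date("2016-11-19"), colour = "green")
  out <- detect_overlap(preg, ep, d, cfg)
  expect_identical(sort(out$overlap_kind),
                   c("pregnancy_started_during_treatment",
                     "retinoid_started_during_pregnancy"))
})

test_that("overlap detection equals the brute-force triple scan on a busy cohort", {
  sim <- simulate_cdm(busy_scenario(17, n = 1000), cfg)
  eps <- build_all_episodes(sim$drugs, cfg)
  reps <- eps[eps$drug_class %in% names(cfg$retinoid_atc), ]
  recon <- filter_by_colour(reconcile_all_pregnancies(sim$pregnancies, cfg),
                            cfg$allowed_colours)
  fast <- detect_overlap(recon, reps, sim$drugs, cfg)
  fast_keys <- sort(paste(fast$person_id, fast$pregnancy_start, fast$overlap_kind))
  expect_identical(fast_keys, brute_force_overlap(recon, reps, sim$drugs, cfg))
  expect_gt(nrow(fast), 0)
})

test_that("full stream completeness recovers every pregnancy as green", {
  full <- list(birth_registry = c(start = 1, end = 1),
               admin_diagnosis = c(start = 1, end = 1),
               eurocat = c(start = 1, end = 1),
               tailored = c(start = 1, end = 1))
  sim <- simulate_cdm(busy_scenario(19, n = 400,
                                    preg_stream_completeness = full), cfg)
  recon <- reconcile_all_pregnancies(sim$pregnancies, cfg)
  expect_identical(nrow(recon), nrow(sim$ledger_pregnancies))
  expect_true(all(recon$colour == "green"))
  got <- recon[order(recon$person_id, recon$start), ]
  want <- sim$ledger_pregnancies[order(sim$ledger_pregnancies$person_id,
                                       sim$ledger_pregnancies$start_true), ]
  expect_identical(got$start, want$start_true)
  expect_identical(got$end, want$end_true)
})

test_that("lower end-date completeness shifts colours away from green/yellow", {
  lower_end <- function(p) list(
    birth_registry = c(start = 0.6, end = p),
    admin_diagnosis = c(start = 0.4, end = p),
    eurocat = c(start = 0.5, end = p),
    tailored = c(start = 0.2, end = p))
  n_end_recorded <- sapply(c(0.9, 0.3), function(p) {
    sim <- simulate_cdm(busy_scenario(23, n = 500,
                                      preg_stream_completeness = lower_end(p)),
                        cfg)
    recon <- reconcile_all_pregnancies(sim$pregnancies, cfg)
    sum(recon$colour %in% c("green", "yellow"))
  })
  expect_gt(n_end_recorded[1], n_end_recorded[2])
})

test_that("rate arithmetic per 1,000 users matches hand calculation", {
  r <- pregnancy_rates(18, 47521, 0, 12893, cfg)
  expect_equal(r$rate_pre, 1000 * 18 / 47521)
  expect_equal(r$rate_post, 0)
  expect_false(r$mask_pre)
  r2 <- pregnancy_rates(3, 1000, 15, 36055, cfg)
  expect_true(r2$mask_pre)
  expect_false(r2$mask_post)
  expect_lt(r2$rd_ci99_low, r2$rate_difference)
  expect_gt(r2$rd_ci99_high, r2$rate_difference)
  expect_error(pregnancy_rates(1, 0, 1, 10, cfg), "positive")
})
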