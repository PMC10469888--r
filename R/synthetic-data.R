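# Seeded generator for the four study tables plus a ground-truth ledger.
# It emulates the statistical structure the analysis assumes: a cohort of
# females of childbearing age observed 2010-2020; retinoid initiations with
# a winter-peak / mid-July-trough cosine seasonality and optional
# post-intervention level and trend changes; refill records with gaps drawn
# below the 30-day merge threshold inside an episode and above the 90-day
# discontinuation threshold between episodes, so the truth is unambiguous;
# contraceptive histories; planted discontinuation-reason markers; and
# pregnancies reported through the four source streams with configurable
# per-stream date completeness.

#' Simulation scenario
#'
#' Parameters of the synthetic electronic-health-database generator. Default
#' values describe the emulated study conditions: baseline incidence 0.2 new
#' users per 1,000 person-months (the order observed pre-intervention in the
#' Danish register), a 30% summer dip, null intervention effects (the study
#' period showed no significant level or trend change), about three records
#' per episode of exact 30-day supplies, and a pregnancy rate of 60 per
#' 1,000 person-years across ages 16-44.
#'
#' @param n_persons Cohort size.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @param baseline_incidence New retinoid users per 1,000 person-months.
#' @param seasonal_amplitude Relative depth of the mid-July trough, in
#'   `[0, 1)`.
#' @param intervention_month Month index (from study start) at which level
#'   and trend changes apply; defaults to the configured RMM implementation
#'   month at generation time when `NULL`.
#' @param level_change Additive change to the monthly initiation rate (per
#'   1,000 person-months) from the intervention month on.
#' @param trend_change Additive change to the monthly slope (per 1,000
#'   person-months per month) after the intervention.
#' @param mean_rx_per_episode Mean records per episode (1 + Poisson).
#' @param days_supply_mean Exact days of supply written on every retinoid
#'   record.
#' @param contraception_prevalence Fraction of women with a contraceptive
#'   history.
#' @param pregnancy_rate Pregnancies per 1,000 person-years among women aged
#'   16-44.
#' @param preg_stream_completeness Named list per stream of
#'   `c(start = p, end = p)` recording probabilities.
#' @param adr_prob,folic_prob,pregtest_prob Per-discontinuation probability
#'   of an adverse-drug-reaction marker, a folic-acid record (pregnancy
#'   wish), and a pregnancy test around each initiation.
#' @param male_fraction Fraction of records carrying male sex, exercised by
#'   the population filter.
#' @return A list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(n_persons = 4000L,
                                seed = 1L,
                                baseline_incidence = 0.2,
                                seasonal_amplitude = 0.3,
                                intervention_month = NULL,
                                level_change = 0,
                                trend_change = 0,
                                mean_rx_per_episode = 3,
                                days_supply_mean = 30L,
                                contraception_prevalence = 0.25,
                                pregnancy_rate = 60,
                                preg_stream_completeness = list(
                                  birth_registry = c(start = 0.9, end = 0.95),
                                  admin_diagnosis = c(start = 0.5, end = 0.7),
                                  eurocat = c(start = 0.6, end = 0.8),
                                  tailored = c(start = 0.2, end = 0.3)),
                                adr_prob = 0.05,
                                folic_prob = 0.03,
                                pregtest_prob = 0.1,
                                male_fraction = 0.02) {
  sc <- structure(as.list(environment()), class = "simulation_scenario")
  stopifnot(sc$n_persons >= 1,
            sc$baseline_incidence >= 0,
            sc$seasonal_amplitude >= 0, sc$seasonal_amplitude < 1,
            sc$mean_rx_per_episode >= 1,
            sc$days_supply_mean >= 1,
            sc$pregnancy_rate >= 0)
  probs <- c(sc$contraception_prevalence, sc$adr_prob, sc$folic_prob,
             sc$pregtest_prob, sc$male_fraction,
             unlist(sc$preg_stream_completeness))
  stopifnot(all(probs >= 0 & probs <= 1))
  sc
}

#' Expected monthly initiation rate of a scenario
#'
#' The hazard the generator realises, per 1,000 person-months: baseline with
#' a cosine seasonal term (trough mid-July, peak mid-January), plus the
#' post-intervention level and trend changes, floored at zero.
#'
#' @param scenario A [simulation_scenario()].
#' @param months Integer month indices.
#' @param moy Calendar months-of-year (1-12) for `months`.
#' @param intervention_month Resolved intervention month index.
#' @return Numeric rate vector (per 1,000 person-months).
#' @export
scenario_monthly_rate <- function(scenario, months, moy, intervention_month) {
  base <- scenario$baseline_incidence *
    (1 - scenario$seasonal_amplitude * cos(2 * pi * (moy - 7) / 12))
  post <- months >= intervention_month
  rate <- base + scenario$level_change * post +
    scenario$trend_change * (months - intervention_month) * post
  pmax(rate, 0)
}

#' Generate the synthetic study tables and ground-truth ledger
#'
#' Deterministic given `scenario$seed`. Returns the four common-data-model
#' tables (persons, drugs, events, pregnancies) together with two ledgers:
#' one row per true treatment episode (with its discontinuation status and
#' reason, computed from what was planted) and one per true pregnancy (with
#' true and reconstruction-expected dates and the expected certainty colour,
#' given which streams recorded which dates). A small monthly-truth table
#' records the realised eligible counts and initiations against the
#' specified hazard.
#'
#' @param scenario A [simulation_scenario()].
#' @param cfg A [study_config()].
#' @return List of class `"cdm_simulation"` with elements `persons`,
#'   `drugs`, `events`, `pregnancies`, `ledger_episodes`,
#'   `ledger_pregnancies`, `monthly_truth`, `scenario`.
#' @export
simulate_cdm <- function(scenario, cfg = study_config()) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_persons
  n_months <- n_study_months(cfg)
  months <- seq_len(n_months) - 1L
  m_starts <- month_index_start(months, cfg$study_start)
  m_ends <- month_index_end(months, cfg$study_start)
  moy <- month_of_year(months, cfg$study_start)
  int_month <- scenario$intervention_month %||%
    month_index(rmm_gap(cfg)[2], cfg$study_start)
  if (int_month < 0L || int_month >= n_months)
    stop("intervention_month outside the study window", call. = FALSE)

  ## ---- persons -----------------------------------------------------------
  person_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < scenario$male_fraction, "M", "F")
  age0 <- stats::runif(n, 6, 54)          # age at study start
  birth_date <- cfg$study_start - round(age0 * 365.25)
  full_start <- stats::runif(n) < 0.8
  obs_start <- cfg$study_start +
    ifelse(full_start, 0, sample.int(6 * 365, n, replace = TRUE))
  full_end <- stats::runif(n) < 0.9
  span <- as.numeric(cfg$study_end - obs_start)
  obs_end <- obs_start + ifelse(full_end, span,
                                365 + round(stats::runif(n) * pmax(span - 365, 0)))
  obs_end <- pmin(obs_end, cfg$study_end)
  persons <- data.frame(person_id = person_id, sex = sex,
                        birth_date = as.Date(birth_date, origin = "1970-01-01"),
                        obs_start = as.Date(obs_start, origin = "1970-01-01"),
                        obs_end = as.Date(obs_end, origin = "1970-01-01"))

  ## ---- retinoid initiations ---------------------------------------------
  rate <- scenario_monthly_rate(scenario, months, moy, int_month)
  supply <- as.integer(scenario$days_supply_mean)
  classes <- retinoid_classes(cfg)
  class_prob <- c(0.80, 0.15, 0.05)       # isotretinoin dominates in practice

  drugs <- list(); events <- list(); led_ep <- list()
  next_allowed <- rep(cfg$study_start - 1L, n)
  monthly_truth <- data.frame(month = months, rate = rate,
                              eligible = 0L, initiations = 0L)
  for (m in months) {
    elig <- in_study_population(persons, m, cfg) &
      persons$obs_end >= m_ends[m + 1L] &
      m_starts[m + 1L] > next_allowed
    monthly_truth$eligible[m + 1L] <- sum(elig)
    if (rate[m + 1L] <= 0 || !any(elig)) next
    hit <- which(elig & stats::runif(n) < rate[m + 1L] / 1000)
    monthly_truth$initiations[m + 1L] <- length(hit)
    for (p in hit) {
      start <- m_starts[m + 1L] + sample.int(28L, 1L) - 1L
      n_rx <- 1L + stats::rpois(1L, max(scenario$mean_rx_per_episode - 1, 0))
      dates <- start
      for (j in seq_len(n_rx - 1L)) {
        nxt <- dates[length(dates)] + supply + sample.int(26L, 1L) - 1L
        if (nxt + supply - 1L > persons$obs_end[p]) break
        dates <- c(dates, nxt)
      }
      cls <- sample(classes, 1L, prob = class_prob)
      drugs[[length(drugs) + 1L]] <- data.frame(
        person_id = person_id[p], atc_code = cfg$retinoid_atc[[cls]],
        record_date = dates,
        record_type = ifelse(stats::runif(length(dates)) < 0.7,
                             "dispensing", "prescription"),
        days_supply = supply)
      ep_end <- dates[length(dates)] + supply - 1L
      led_ep[[length(led_ep) + 1L]] <- data.frame(
        person_id = person_id[p], drug_class = cls, start = start,
        end = ep_end, n_records = length(dates),
        last_record_date = dates[length(dates)])
      next_allowed[p] <- ep_end + cfg$discontinuation_gap_days + 1L
      if (stats::runif(1) < scenario$pregtest_prob) {
        off <- sample.int(91L, 1L) - 1L
        tdate <- if (start - off >= persons$obs_start[p]) start - off
                 else start + off
        events[[length(events) + 1L]] <- data.frame(
          person_id = person_id[p], event_date = tdate,
          event_kind = "pregnancy_test", event_code = "PT")
      }
    }
  }
  ledger_episodes <- if (length(led_ep))
    do.call(rbind, c(led_ep, list(make.row.names = FALSE)))
  else data.frame(person_id = character(), drug_class = character(),
                  start = as.Date(character()), end = as.Date(character()),
                  n_records = integer(), last_record_date = as.Date(character()))

  ## ---- discontinuation truth and planted reasons ------------------------
  le <- ledger_episodes
  if (nrow(le)) {
    obs_end_ep <- persons$obs_end[match(le$person_id, persons$person_id)]
    le$assessable <- le$last_record_date + cfg$discontinuation_gap_days <=
      pmin(obs_end_ep, cfg$study_end)
    le$discontinued <- le$assessable     # no same-class record follows, by design
    le$planted_reason <- NA_character_
    for (i in which(le$discontinued)) {
      u <- stats::runif(1)
      cls <- le$drug_class[i]
      d0 <- le$end[i]
      off <- sample.int(60L, 1L)
      if (cls %in% c("isotretinoin", "alitretinoin") && u < scenario$folic_prob) {
        le$planted_reason[i] <- "pregnancy_wish"
        drugs[[length(drugs) + 1L]] <- data.frame(
          person_id = le$person_id[i], atc_code = cfg$folic_atc,
          record_date = d0 + off, record_type = "prescription",
          days_supply = 30L)
      } else if (u < scenario$folic_prob + scenario$adr_prob) {
        le$planted_reason[i] <- "adr"
        if (stats::runif(1) < 0.5) {
          events[[length(events) + 1L]] <- data.frame(
            person_id = le$person_id[i], event_date = d0 + off,
            event_kind = "adr_diagnosis", event_code = cfg$adr_codes[1])
        } else {
          drugs[[length(drugs) + 1L]] <- data.frame(
            person_id = le$person_id[i],
            atc_code = paste0(cfg$antidepressant_atc_prefix, "B06"),
            record_date = d0 + off, record_type = "prescription",
            days_supply = 30L)
        }
      }
    }
  } else {
    le$assessable <- logical(); le$discontinued <- logical()
    le$planted_reason <- character()
  }

  ## ---- contraception -----------------------------------------------------
  women <- which(persons$sex == "F")
  with_contra <- women[stats::runif(length(women)) <
                         scenario$contraception_prevalence]
  for (p in with_contra) {
    span_p <- as.numeric(persons$obs_end[p] - persons$obs_start[p])
    if (span_p < 400) next
    start <- persons$obs_start[p] + round(stats::runif(1) * (span_p - 380))
    if (stats::runif(1) < 0.5) {
      drugs[[length(drugs) + 1L]] <- data.frame(
        person_id = person_id[p], atc_code = "G02BA03",
        record_date = start, record_type = "dispensing",
        days_supply = cfg$device_supply_days)
    } else {
      k <- 1L + stats::rpois(1L, 5)
      dates <- start
      for (j in seq_len(k - 1L)) {
        nxt <- dates[length(dates)] + 28L + sample.int(21L, 1L) - 1L
        if (nxt + 27L > persons$obs_end[p]) break
        dates <- c(dates, nxt)
      }
      drugs[[length(drugs) + 1L]] <- data.frame(
        person_id = person_id[p], atc_code = "G03AA07",
        record_date = dates, record_type = "dispensing", days_supply = 28L)
    }
  }

  ## ---- pregnancies -------------------------------------------------------
  preg_rows <- list(); led_pg <- list()
  q <- scenario$pregnancy_rate / 1000 / 12
  next_preg <- rep(cfg$study_start - 1L, n)
  comp <- scenario$preg_stream_completeness
  for (m in months) {
    age_m <- age_on(persons$birth_date, m_starts[m + 1L])
    fertile <- persons$sex == "F" & age_m >= 16 & age_m <= 44 &
      persons$obs_start <= m_starts[m + 1L] &
      persons$obs_end >= m_ends[m + 1L] + 280 &
      m_starts[m + 1L] > next_preg
    if (q <= 0 || !any(fertile)) next
    hit <- which(fertile & stats::runif(n) < q)
    for (p in hit) {
      start <- m_starts[m + 1L] + sample.int(28L, 1L) - 1L
      birth <- stats::runif(1) < 0.8
      duration <- if (birth) 273L else
        273L - as.integer(round(pmin(pmax(stats::rnorm(1, 180, 30), 60), 240)))
      end <- start + duration
      next_preg[p] <- start + 600L
      streams <- if (birth) {
        c("birth_registry", if (stats::runif(1) < 0.5) "admin_diagnosis")
      } else {
        if (stats::runif(1) < 0.7) "admin_diagnosis" else "tailored"
      }
      if (stats::runif(1) < 0.02) streams <- c(streams, "eurocat")
      rec_start_any <- FALSE; rec_end_any <- FALSE
      end_rec_streams <- character()
      gest_by_stream <- list()
      for (s in streams) {
        rs <- stats::runif(1) < comp[[s]][["start"]]
        re <- stats::runif(1) < comp[[s]][["end"]]
        ga <- if (s == "birth_registry" && stats::runif(1) < 0.5)
          duration else NA_integer_
        preg_rows[[length(preg_rows) + 1L]] <- data.frame(
          person_id = person_id[p], stream = s,
          record_date = end - (sample.int(15L, 1L) - 1L),
          recorded_start = if (rs) start else as.Date(NA),
          recorded_end = if (re) end else as.Date(NA),
          gestational_age_days = ga)
        rec_start_any <- rec_start_any || rs
        if (re) end_rec_streams <- c(end_rec_streams, s)
        rec_end_any <- rec_end_any || re
        gest_by_stream[[s]] <- ga
      }
      # expected reconciled dates: recorded dates are the truth when present;
      # otherwise the 273-day (or recorded gestational-age) imputation
      if (rec_start_any && rec_end_any) {
        colour <- "green"; ostart <- start; oend <- end
      } else if (rec_end_any) {
        colour <- "yellow"; oend <- end
        top <- end_rec_streams[order(stream_priority[end_rec_streams])][1]
        ga <- gest_by_stream[[top]]
        ostart <- end - (if (!is.null(ga) && !is.na(ga)) ga else GESTATION_DAYS)
      } else if (rec_start_any) {
        colour <- "blue"; ostart <- start; oend <- start + GESTATION_DAYS
      } else {
        colour <- "red"
        anchor <- preg_rows[[length(preg_rows)]]$record_date  # single-stream case
        ostart <- anchor - 136L; oend <- ostart + GESTATION_DAYS
      }
      led_pg[[length(led_pg) + 1L]] <- data.frame(
        person_id = person_id[p], start_true = start, end_true = end,
        observed_start = ostart, observed_end = oend, colour = colour,
        outcome = if (birth) "birth" else "other",
        streams = paste(sort(unique(streams)), collapse = ","))
    }
  }
  ledger_pregnancies <- if (length(led_pg))
    do.call(rbind, c(led_pg, list(make.row.names = FALSE)))
  else data.frame(person_id = character(), start_true = as.Date(character()),
                  end_true = as.Date(character()),
                  observed_start = as.Date(character()),
                  observed_end = as.Date(character()), colour = character(),
                  outcome = character(), streams = character())

  ## ---- ledger reasons (precedence pregnancy > wish > adr > unknown) -----
  if (nrow(le)) {
    keep_pg <- ledger_pregnancies[
      ledger_pregnancies$colour %in% cfg$allowed_colours, , drop = FALSE]
    pg_by_person <- split(keep_pg$observed_start, keep_pg$person_id)
    le$reason <- NA_character_
    for (i in which(le$discontinued)) {
      d0 <- le$end[i]
      ps <- pg_by_person[[le$person_id[i]]]
      le$reason[i] <- if (!is.null(ps) &&
                          any(ps > d0 & as.numeric(ps - d0) <= cfg$reason_window_days))
        "pregnancy"
      else if (identical(le$planted_reason[i], "pregnancy_wish")) "pregnancy_wish"
      else if (identical(le$planted_reason[i], "adr")) "adr"
      else "unknown"
    }
  } else le$reason <- character()

  drugs_df <- if (length(drugs))
    do.call(rbind, c(drugs, list(make.row.names = FALSE)))
  else data.frame(person_id = character(), atc_code = character(),
                  record_date = as.Date(character()),
                  record_type = character(), days_supply = integer())
  events_df <- if (length(events))
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  else data.frame(person_id = character(), event_date = as.Date(character()),
                  event_kind = character(), event_code = character())
  preg_df <- if (length(preg_rows))
    do.call(rbind, c(preg_rows, list(make.row.names = FALSE)))
  else data.frame(person_id = character(), stream = character(),
                  record_date = as.Date(character()),
                  recorded_start = as.Date(character()),
                  recorded_end = as.Date(character()),
                  gestational_age_days = integer())
  o <- order(drugs_df$person_id, drugs_df$record_date, drugs_df$atc_code)
  drugs_df <- drugs_df[o, , drop = FALSE]
  rownames(drugs_df) <- NULL

  structure(list(persons = persons, drugs = drugs_df, events = events_df,
                 pregnancies = preg_df, ledger_episodes = le,
                 ledger_pregnancies = ledger_pregnancies,
                 monthly_truth = monthly_truth, scenario = scenario),
            class = "cdm_simulation")
}

#' Write a simulation to a directory of CSV files
#'
#' Writes the four validated CDM tables plus the two ledger files
#' (`ledger_episodes.csv`, `ledger_pregnancies.csv`) and the monthly truth.
#'
#' @param sim A `"cdm_simulation"` from [simulate_cdm()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cdm_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cdm_table(sim$persons, file.path(dir, "persons.csv"), "persons")
  write_cdm_table(sim$drugs, file.path(dir, "drugs.csv"), "drugs")
  write_cdm_table(sim$events, file.path(dir, "events.csv"), "events")
  write_cdm_table(sim$pregnancies, file.path(dir, "pregnancies.csv"),
                  "pregnancies")
  for (nm in c("ledger_episodes", "ledger_pregnancies", "monthly_truth")) {
    out <- sim[[nm]]
    for (col in names(out))
      if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]])
    utils::write.csv(out, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}
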