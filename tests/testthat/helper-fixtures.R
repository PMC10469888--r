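# Shared fixtures, built in code. Scenarios are scaled so the whole suite
# runs in minutes on one CPU.

cfg_default <- study_config()

# single-person drug-record table for episode unit tests
drug_rows <- function(dates, supply = 30L, atc = "D10BA01", person = "p1",
                      type = "dispensing") {
  n <- length(dates)
  data.frame(person_id = rep_len(person, n), atc_code = rep_len(atc, n),
             record_date = as.Date(dates), record_type = rep_len(type, n),
             days_supply = rep_len(as.integer(supply), n))
}

person_row <- function(person = "p1", birth = "1990-01-01",
                       obs_start = "2010-01-01", obs_end = "2020-12-31",
                       sex = "F") {
  data.frame(person_id = person, sex = sex, birth_date = as.Date(birth),
             obs_start = as.Date(obs_start), obs_end = as.Date(obs_end))
}

preg_source_row <- function(person = "p1", stream = "birth_registry",
                            record_date, recorded_start = NA,
                            recorded_end = NA, gest = NA_integer_) {
  data.frame(person_id = person, stream = stream,
             record_date = as.Date(record_date),
             recorded_start = as.Date(recorded_start),
             recorded_end = as.Date(recorded_end),
             gestational_age_days = as.integer(gest))
}

# moderately busy synthetic cohort reused across oracle tests; dots override
busy_scenario <- function(seed, n = 500L, ...) {
  args <- utils::modifyList(
    list(n_persons = n, seed = seed, baseline_incidence = 2,
         pregnancy_rate = 80),
    list(...))
  do.call(simulation_scenario, args)
}

# brute-force overlap scan: every (pregnancy, episode) and
# (pregnancy, retinoid record) pair, one case per pregnancy per kind
brute_force_overlap <- function(pregnancies, episodes, drugs, cfg) {
  drugs <- prioritise_dispensing(drugs)
  drugs$drug_class <- atc_to_class(drugs$atc_code, cfg)
  rdrugs <- drugs[drugs$drug_class %in% names(cfg$retinoid_atc), ]
  out <- list()
  for (i in seq_len(nrow(pregnancies))) {
    p <- pregnancies[i, ]
    started_during <- FALSE
    retinoid_during <- FALSE
    for (j in seq_len(nrow(episodes))) {
      e <- episodes[j, ]
      if (e$person_id == p$person_id &&
          p$start >= e$start &&
          p$start <= e$end + cfg$teratogenic_extension_days)
        started_during <- TRUE
    }
    for (j in seq_len(nrow(rdrugs))) {
      d <- rdrugs[j, ]
      if (d$person_id == p$person_id &&
          d$record_date >= p$start && d$record_date <= p$end)
        retinoid_during <- TRUE
    }
    if (started_during)
      out[[length(out) + 1L]] <- paste(p$person_id, p$start,
                                       "pregnancy_started_during_treatment")
    if (retinoid_during)
      out[[length(out) + 1L]] <- paste(p$person_id, p$start,
                                       "retinoid_started_during_pregnancy")
  }
  sort(unlist(out))
}
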