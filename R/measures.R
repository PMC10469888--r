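# Monthly utilisation series in a single long layout:
# series_name, stratum, month (index from study start), numerator,
# denominator, value. Person-month denominators count a person who is
# observed at least one day of the month; months with a zero denominator
# carry an NA value (undefined) rather than a zero.

monthly_series <- function(series_name, stratum, month, numerator,
                           denominator, scale = 1) {
  value <- ifelse(denominator > 0, scale * numerator / denominator, NA_real_)
  data.frame(series_name = series_name, stratum = stratum, month = month,
             numerator = numerator, denominator = denominator, value = value)
}

# Study-population person counts for every month, optionally split by the
# reporting age bands.
population_by_month <- function(persons, cfg, by_age_band = FALSE) {
  months <- seq_len(n_study_months(cfg)) - 1L
  if (!by_age_band) {
    n <- vapply(months, function(m) sum(in_study_population(persons, m, cfg)), 0)
    return(data.frame(month = months, stratum = "overall", denominator = n))
  }
  out <- lapply(months, function(m) {
    inpop <- in_study_population(persons, m, cfg)
    band <- age_band(age_on(persons$birth_date[inpop],
                            month_index_start(m, cfg$study_start)))
    tab <- table(factor(band, levels = c("12-<21", "21-<31", "31-<41", "41-55")))
    data.frame(month = m, stratum = names(tab), denominator = as.integer(tab))
  })
  do.call(rbind, out)
}

#' Monthly incidence of new use per 1,000 person-months
#'
#' A person is incidence-evaluable in a month when in the study population
#' and observed for the full lookback (365 days) before the month start. An
#' incident user has a qualifying record in the month and no same-class
#' record during the lookback window.
#'
#' @param drugs Drugs table.
#' @param persons Persons table.
#' @param cfg A [study_config()].
#' @param drug_class One retinoid class, or `"retinoid_any"` (default) to
#'   pool all three.
#' @return Long-format monthly series (value per 1,000 person-months).
#' @export
monthly_incidence <- function(drugs, persons, cfg, drug_class = "retinoid_any") {
  drugs <- prioritise_dispensing(drugs)
  drugs$drug_class <- atc_to_class(drugs$atc_code, cfg)
  keep <- if (drug_class == "retinoid_any")
    drugs$drug_class %in% retinoid_classes(cfg)
  else drugs$drug_class == drug_class
  d <- drugs[keep & !is.na(drugs$drug_class), , drop = FALSE]

  months <- seq_len(n_study_months(cfg)) - 1L
  m_starts <- month_index_start(months, cfg$study_start)

  # evaluable denominator: in population and >= lookback_days of observation
  # before the month start
  obs_start <- persons$obs_start
  denom <- vapply(months, function(m) {
    sum(in_study_population(persons, m, cfg) &
          obs_start <= m_starts[m + 1L] - cfg$lookback_days)
  }, 0)

  num <- integer(length(months))
  if (nrow(d)) {
    d <- d[d$record_date >= cfg$study_start & d$record_date <= cfg$study_end, ]
    d$month <- month_index(d$record_date, cfg$study_start)
    dates_by_person <- split(d$record_date, d$person_id)
    # candidate person-months: any record in the month
    cand <- unique(d[c("person_id", "month")])
    prow <- match(cand$person_id, persons$person_id)
    for (i in seq_len(nrow(cand))) {
      m <- cand$month[i]
      ms <- m_starts[m + 1L]
      p <- prow[i]
      if (is.na(p)) next
      if (!in_study_population(persons[p, , drop = FALSE], m, cfg)) next
      if (persons$obs_start[p] > ms - cfg$lookback_days) next
      dates <- dates_by_person[[cand$person_id[i]]]
      if (any(dates < ms & dates >= ms - cfg$lookback_days)) next
      num[m + 1L] <- num[m + 1L] + 1L
    }
  }
  monthly_series("incidence", drug_class, months, num, denom, scale = 1000)
}

#' Monthly prevalence of use per 1,000 persons
#'
#' A person is a prevalent user in a month when a treatment episode overlaps
#' at least one day of it; the denominator is the study population of the
#' month.
#'
#' @param episodes Retinoid episodes.
#' @inheritParams monthly_incidence
#' @return Long-format monthly series (value per 1,000 persons).
#' @export
monthly_prevalence <- function(episodes, persons, cfg,
                               drug_class = "retinoid_any") {
  keep <- if (drug_class == "retinoid_any")
    episodes$drug_class %in% retinoid_classes(cfg)
  else episodes$drug_class == drug_class
  eps <- episodes[keep, , drop = FALSE]

  months <- seq_len(n_study_months(cfg)) - 1L
  pop <- population_by_month(persons, cfg)
  num <- integer(length(months))
  if (nrow(eps)) {
    pm <- episode_person_months(eps, cfg)
    prow <- match(pm$person_id, persons$person_id)
    ok <- vapply(seq_len(nrow(pm)), function(i)
      in_study_population(persons[prow[i], , drop = FALSE], pm$month[i], cfg),
      TRUE)
    pm <- pm[ok, , drop = FALSE]
    tab <- table(factor(pm$month, levels = months))
    num <- as.integer(tab)
  }
  monthly_series("prevalence", drug_class, months, num, pop$denominator,
                 scale = 1000)
}

# distinct person x month pairs with >= 1 exposed day
episode_person_months <- function(eps, cfg) {
  pieces <- lapply(seq_len(nrow(eps)), function(i) {
    s <- max(eps$start[i], cfg$study_start)
    e <- min(eps$end[i], cfg$study_end)
    if (s > e) return(NULL)
    data.frame(person_id = eps$person_id[i],
               month = seq(month_index(s, cfg$study_start),
                           month_index(e, cfg$study_start)))
  })
  unique(do.call(rbind, pieces))
}

#' Monthly discontinuation proportion with a previous-quarter denominator
#'
#' Numerator: assessable discontinuations dated in the month. Denominator:
#' distinct persons with a retinoid episode overlapping the preceding
#' calendar quarter. Months whose preceding quarter had no users are flagged
#' undefined (NA).
#'
#' @param episodes Discontinuation-flagged retinoid episodes.
#' @param cfg A [study_config()].
#' @return Long-format monthly series (value is a proportion).
#' @export
discontinuation_rate <- function(episodes, cfg) {
  eps <- episodes[episodes$drug_class %in% retinoid_classes(cfg), , drop = FALSE]
  months <- seq_len(n_study_months(cfg)) - 1L

  num <- integer(length(months))
  disc <- eps[isTRUE_vec(eps$discontinued), , drop = FALSE]
  if (nrow(disc)) {
    dm <- month_index(disc$discontinuation_date, cfg$study_start)
    tab <- table(factor(dm, levels = months))
    num <- as.integer(tab)
  }
  pm <- if (nrow(eps)) episode_person_months(eps, cfg) else
    data.frame(person_id = character(), month = integer())
  pm$quarter <- pm$month %/% 3L
  users_by_quarter <- tapply(pm$person_id, pm$quarter,
                             function(x) length(unique(x)))
  denom <- vapply(months, function(m) {
    q_prev <- m %/% 3L - 1L
    if (q_prev < 0L) return(0L)
    n <- users_by_quarter[as.character(q_prev)]
    if (is.na(n)) 0L else as.integer(n)
  }, 0L)
  monthly_series("discontinuation", "retinoid_any", months, num, denom)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Monthly contraception proportions around retinoid initiation
#'
#' Two series over retinoid episode starts: `contraception_covered` - the
#' fraction of starts falling inside a contraception coverage interval; and
#' `contraception_prior90` - the fraction with a contraceptive episode
#' starting within the 90 days before the retinoid start.
#'
#' @param retinoid_episodes Retinoid episodes.
#' @param coverage Coverage intervals from [contraception_coverage()].
#' @param contra_episodes Contraceptive episodes (any class) for the
#'   prior-start series.
#' @param cfg A [study_config()].
#' @return Long-format series, both per initiation month.
#' @export
contraception_proportions <- function(retinoid_episodes, coverage,
                                      contra_episodes, cfg) {
  eps <- retinoid_episodes[
    retinoid_episodes$drug_class %in% retinoid_classes(cfg), , drop = FALSE]
  months <- seq_len(n_study_months(cfg)) - 1L
  denom <- num_a <- num_b <- integer(length(months))
  cov_by_person <- split(coverage, coverage$person_id)
  cstart_by_person <- split(contra_episodes$start, contra_episodes$person_id)
  w <- cfg$reason_window_days
  for (i in seq_len(nrow(eps))) {
    s <- eps$start[i]
    if (s < cfg$study_start || s > cfg$study_end) next
    m <- month_index(s, cfg$study_start)
    denom[m + 1L] <- denom[m + 1L] + 1L
    cv <- cov_by_person[[eps$person_id[i]]]
    if (!is.null(cv) && any(s >= cv$start & s <= cv$end))
      num_a[m + 1L] <- num_a[m + 1L] + 1L
    cs <- cstart_by_person[[eps$person_id[i]]]
    if (!is.null(cs) && any(cs <= s & as.numeric(s - cs) <= w))
      num_b[m + 1L] <- num_b[m + 1L] + 1L
  }
  rbind(
    monthly_series("contraception_covered", "retinoid_any", months, num_a, denom),
    monthly_series("contraception_prior90", "retinoid_any", months, num_b, denom)
  )
}

#' Monthly pregnancy-testing proportions and testing incidence
#'
#' `pregtest_around_start`: per month of retinoid initiation, the fraction of
#' initiations with at least one pregnancy-test record within 90 days before
#' or after the start. `pregtest_per_pm`: witnessed tests per 1,000
#' person-months of the study population.
#'
#' @param events Events table.
#' @param retinoid_episodes Retinoid episodes.
#' @param persons Persons table.
#' @param cfg A [study_config()].
#' @return Long-format series (two series stacked).
#' @export
pregnancy_testing_proportions <- function(events, retinoid_episodes,
                                          persons, cfg) {
  eps <- retinoid_episodes[
    retinoid_episodes$drug_class %in% retinoid_classes(cfg), , drop = FALSE]
  tests <- events[events$event_kind == "pregnancy_test", , drop = FALSE]
  tests_by_person <- split(tests$event_date, tests$person_id)
  months <- seq_len(n_study_months(cfg)) - 1L
  denom <- num <- integer(length(months))
  w <- cfg$reason_window_days
  for (i in seq_len(nrow(eps))) {
    s <- eps$start[i]
    if (s < cfg$study_start || s > cfg$study_end) next
    m <- month_index(s, cfg$study_start)
    denom[m + 1L] <- denom[m + 1L] + 1L
    td <- tests_by_person[[eps$person_id[i]]]
    if (!is.null(td) && any(abs(as.numeric(td - s)) <= w))
      num[m + 1L] <- num[m + 1L] + 1L
  }
  pop <- population_by_month(persons, cfg)
  tnum <- integer(length(months))
  intests <- tests[tests$event_date >= cfg$study_start &
                     tests$event_date <= cfg$study_end, , drop = FALSE]
  if (nrow(intests)) {
    tm <- month_index(intests$event_date, cfg$study_start)
    tnum <- as.integer(table(factor(tm, levels = months)))
  }
  rbind(
    monthly_series("pregtest_around_start", "retinoid_any", months, num, denom),
    monthly_series("pregtest_per_pm", "overall", months, tnum,
                   pop$denominator, scale = 1000)
  )
}

#' Apply small-cell masking to a series for display
#'
#' Returns a character rendering of the numerator with counts below the
#' threshold shown as `"<5"`. Masking is applied only on export for
#' human-readable reports; machine outputs keep exact values.
#'
#' @param series A long-format monthly series.
#' @param cfg A [study_config()].
#' @return `series` with an additional `numerator_display` column.
#' @export
mask_small_cells <- function(series, cfg) {
  thr <- cfg$small_cell_threshold
  series$numerator_display <- ifelse(
    series$numerator > 0 & series$numerator < thr,
    paste0("<", thr), as.character(series$numerator))
  series
}
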