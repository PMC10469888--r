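# Treatment-episode construction. A drug record covers
# [record_date, record_date + days_supply - 1]; successive coverage
# intervals separated by a gap of fewer than `episode_gap_days` days are
# merged into one episode, during which the person is assumed exposed.
# Discontinuation is the absence of any same-class record within
# `discontinuation_gap_days` after the episode's last record.

default_supply_for_class <- function(drug_class, cfg) {
  ifelse(drug_class == "contraceptive_user_independent",
         cfg$device_supply_days, cfg$default_days_supply)
}

#' Build treatment episodes for one person and drug class
#'
#' @param records Drugs-table rows for a single person and a single drug
#'   class, sorted by `record_date`. Missing `days_supply` is filled with the
#'   class default (30 days; the device coverage for user-independent
#'   contraceptives).
#' @param cfg A [study_config()].
#' @param drug_class Class label attached to the output (inferred from the
#'   first record's ATC when omitted).
#' @return A `data.frame` with one row per episode: `person_id`,
#'   `drug_class`, `start`, `end`, `n_records`, `last_record_date`.
#' @examples
#' cfg <- study_config()
#' recs <- data.frame(person_id = "p1", atc_code = "D10BA01",
#'                    record_date = as.Date(c("2015-01-01", "2015-02-20")),
#'                    record_type = "dispensing", days_supply = 30L)
#' build_episodes(recs, cfg)  # one merged episode 2015-01-01 .. 2015-03-21
#' @export
build_episodes <- function(records, cfg, drug_class = NULL) {
  if (nrow(records) == 0L) return(empty_episodes())
  if (length(unique(records$person_id)) > 1L)
    stop("build_episodes expects records of a single person", call. = FALSE)
  if (is.unsorted(records$record_date))
    stop("records must be sorted by record_date", call. = FALSE)
  if (is.null(drug_class)) {
    drug_class <- atc_to_class(records$atc_code[1], cfg)
    if (is.na(drug_class)) drug_class <- records$atc_code[1]
  }
  supply <- records$days_supply
  supply[is.na(supply)] <- default_supply_for_class(drug_class, cfg)
  cov_start <- records$record_date
  cov_end <- records$record_date + supply - 1L

  ep_start <- cov_start[1]
  ep_end <- cov_end[1]
  ep_n <- 1L
  ep_last <- cov_start[1]
  out <- list()
  for (i in seq_len(nrow(records))[-1]) {
    gap <- as.numeric(cov_start[i] - ep_end) - 1
    if (gap < cfg$episode_gap_days) {   # merge: exposed through the gap
      ep_end <- max(ep_end, cov_end[i])
      ep_n <- ep_n + 1L
      ep_last <- max(ep_last, cov_start[i])
    } else {
      out[[length(out) + 1L]] <- list(ep_start, ep_end, ep_n, ep_last)
      ep_start <- cov_start[i]; ep_end <- cov_end[i]
      ep_n <- 1L; ep_last <- cov_start[i]
    }
  }
  out[[length(out) + 1L]] <- list(ep_start, ep_end, ep_n, ep_last)
  data.frame(
    person_id = records$person_id[1],
    drug_class = drug_class,
    start = as.Date(vapply(out, function(x) format(x[[1]]), "")),
    end = as.Date(vapply(out, function(x) format(x[[2]]), "")),
    n_records = vapply(out, function(x) x[[3]], 1L),
    last_record_date = as.Date(vapply(out, function(x) format(x[[4]]), ""))
  )
}

empty_episodes <- function() {
  data.frame(person_id = character(), drug_class = character(),
             start = as.Date(character()), end = as.Date(character()),
             n_records = integer(), last_record_date = as.Date(character()))
}

#' Build episodes for every person and recognised drug class
#'
#' Applies dispensing-over-prescription priority, maps ATC codes to analysis
#' classes, and runs [build_episodes()] per person and class. Records whose
#' ATC maps to no analysis class are ignored.
#'
#' @param drugs A drugs table.
#' @param cfg A [study_config()].
#' @param classes Optional subset of class labels to build.
#' @return Episodes `data.frame` (see [build_episodes()]).
#' @export
build_all_episodes <- function(drugs, cfg, classes = NULL) {
  drugs <- prioritise_dispensing(drugs)
  drugs$drug_class <- atc_to_class(drugs$atc_code, cfg)
  drugs <- drugs[!is.na(drugs$drug_class), , drop = FALSE]
  if (!is.null(classes))
    drugs <- drugs[drugs$drug_class %in% classes, , drop = FALSE]
  if (!nrow(drugs)) return(empty_episodes())
  drugs <- drugs[order(drugs$person_id, drugs$drug_class, drugs$record_date), ]
  pieces <- split(drugs, list(drugs$person_id, drugs$drug_class), drop = TRUE)
  do.call(rbind, c(lapply(pieces, function(g)
    build_episodes(g, cfg, drug_class = g$drug_class[1])),
    list(make.row.names = FALSE)))
}

#' Flag discontinuation of treatment episodes
#'
#' An episode is discontinued when no same-class record for the person falls
#' within `discontinuation_gap_days` after its last record date. Episodes
#' whose assessment window runs past the person's observation end, the study
#' end, or the COVID censor date are flagged not assessable and excluded from
#' discontinuation numerators.
#'
#' @param episodes Episodes from [build_all_episodes()].
#' @param drugs The drugs table the episodes were built from.
#' @param persons The persons table (for observation ends).
#' @param cfg A [study_config()].
#' @return `episodes` with logical columns `assessable`, `discontinued` and a
#'   Date `discontinuation_date` (`NA` unless discontinued).
#' @export
flag_discontinuation <- function(episodes, drugs, persons, cfg) {
  if (!nrow(episodes)) {
    episodes$assessable <- logical(); episodes$discontinued <- logical()
    episodes$discontinuation_date <- as.Date(character())
    return(episodes)
  }
  drugs <- prioritise_dispensing(drugs)
  drugs$drug_class <- atc_to_class(drugs$atc_code, cfg)
  horizon <- min(cfg$study_end,
                 if (!is.null(cfg$covid_censor_end)) cfg$covid_censor_end
                 else cfg$study_end)
  obs_end <- persons$obs_end[match(episodes$person_id, persons$person_id)]
  window_end <- episodes$last_record_date + cfg$discontinuation_gap_days
  assessable <- window_end <= pmin(obs_end, horizon)

  key <- paste(drugs$person_id, drugs$drug_class)
  by_key <- split(drugs$record_date, key)
  ep_key <- paste(episodes$person_id, episodes$drug_class)
  discontinued <- vapply(seq_len(nrow(episodes)), function(i) {
    dates <- by_key[[ep_key[i]]]
    last <- episodes$last_record_date[i]
    !any(dates > last & as.numeric(dates - last) <= cfg$discontinuation_gap_days)
  }, TRUE)
  discontinued <- discontinued & assessable
  episodes$assessable <- assessable
  episodes$discontinued <- discontinued
  episodes$discontinuation_date <- as.Date(ifelse(discontinued,
                                                  format(episodes$end), NA))
  episodes
}

#' Classify the reason for each discontinuation
#'
#' Screens the `reason_window_days` (default 90) after the discontinuation
#' date, with precedence pregnancy > pregnancy wish > adverse drug reaction:
#' \itemize{
#'   \item \emph{pregnancy}: a pregnancy event starts in the window;
#'   \item \emph{pregnancy_wish}: folic acid recorded in the window, for
#'     isotretinoin or alitretinoin episodes only;
#'   \item \emph{adr}: a retinoid-associated ADR diagnosis or an
#'     antidepressant record (depression proxy) in the window;
#'   \item \emph{unknown}: the default.
#' }
#'
#' @param episodes Discontinuation-flagged episodes; only rows with
#'   `discontinued == TRUE` are classified (others get `NA`).
#' @param events Events table.
#' @param drugs Drugs table.
#' @param pregnancy_events Reconciled pregnancies (see
#'   [reconcile_all_pregnancies()]), already filtered to the colours admitted
#'   by the analysis.
#' @param cfg A [study_config()].
#' @return `episodes` with a `reason` column.
#' @export
classify_discontinuation <- function(episodes, events, drugs,
                                     pregnancy_events, cfg) {
  drugs$drug_class <- atc_to_class(drugs$atc_code, cfg)
  folic_by_person <- split(drugs$record_date[drugs$drug_class %in% "folic_acid"],
                           drugs$person_id[drugs$drug_class %in% "folic_acid"])
  antidep_by_person <- split(
    drugs$record_date[drugs$drug_class %in% "antidepressant"],
    drugs$person_id[drugs$drug_class %in% "antidepressant"])
  adr_ev <- events[events$event_kind == "adr_diagnosis" &
                     events$event_code %in% cfg$adr_codes, , drop = FALSE]
  adr_by_person <- split(adr_ev$event_date, adr_ev$person_id)
  preg_by_person <- split(pregnancy_events$start, pregnancy_events$person_id)

  w <- cfg$reason_window_days
  in_window <- function(dates, d0) {
    !is.null(dates) && any(dates > d0 & as.numeric(dates - d0) <= w)
  }
  reason <- rep(NA_character_, nrow(episodes))
  for (i in seq_len(nrow(episodes))) {
    if (!isTRUE(episodes$discontinued[i])) next
    pid <- episodes$person_id[i]
    d0 <- episodes$discontinuation_date[i]
    reason[i] <- if (in_window(preg_by_person[[pid]], d0)) {
      "pregnancy"
    } else if (episodes$drug_class[i] %in% c("isotretinoin", "alitretinoin") &&
               in_window(folic_by_person[[pid]], d0)) {
      "pregnancy_wish"
    } else if (in_window(adr_by_person[[pid]], d0) ||
               in_window(antidep_by_person[[pid]], d0)) {
      "adr"
    } else "unknown"
  }
  episodes$reason <- reason
  episodes
}

#' Contraception coverage intervals per person
#'
#' Coverage is the union of user-independent contraceptive episodes
#' (intra-uterine devices, implants; their record carries the device
#' duration). Hormonal episodes count only when
#' `cfg$include_hormonal_coverage` is `TRUE`: on their own they do not meet
#' the programme's requirement, which pairs them with a barrier method that
#' over-the-counter sales keep invisible to the databases.
#'
#' @param contra_episodes Episodes of the contraceptive classes.
#' @param cfg A [study_config()].
#' @return `data.frame` of `person_id`, `start`, `end` coverage intervals.
#' @export
contraception_coverage <- function(contra_episodes, cfg) {
  keep <- contra_episodes$drug_class == "contraceptive_user_independent"
  if (cfg$include_hormonal_coverage)
    keep <- keep | contra_episodes$drug_class == "contraceptive_hormonal"
  eps <- contra_episodes[keep, , drop = FALSE]
  if (!nrow(eps))
    return(data.frame(person_id = character(), start = as.Date(character()),
                      end = as.Date(character())))
  pieces <- lapply(split(eps, eps$person_id), function(g) {
    iv <- merge_day_intervals(g$start, g$end)
    cbind(person_id = g$person_id[1], iv)
  })
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}
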