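# Pregnancy identification from four source streams (birth registry,
# administrative diagnoses, congenital-anomaly registry, tailored), with
# certainty colours: green = both dates recorded, yellow = end recorded /
# start imputed, blue = start recorded / end imputed, red = both imputed.
# The imputed gestation length is a single documented constant of 273 days.

GESTATION_DAYS <- 273L

stream_priority <- c(birth_registry = 1L, admin_diagnosis = 2L,
                     eurocat = 3L, tailored = 4L)

# Anchor date used for clustering source rows into pregnancies: the recorded
# start when present, else the start implied by the recorded end, else the
# record date itself.
pregnancy_anchor <- function(rec) {
  anchor <- rec$recorded_start
  use_end <- is.na(anchor) & !is.na(rec$recorded_end)
  gest <- ifelse(is.na(rec$gestational_age_days), GESTATION_DAYS,
                 rec$gestational_age_days)
  anchor[use_end] <- rec$recorded_end[use_end] - gest[use_end]
  anchor[is.na(anchor)] <- rec$record_date[is.na(anchor)]
  anchor
}

#' Reconcile one person's pregnancy source records
#'
#' Source rows whose anchor dates fall within one gestation (273 days) of the
#' cluster and are not separated by a recorded pregnancy end are grouped into
#' a single pregnancy. Within a group, stream priority
#' birth registry > administrative diagnosis > anomaly registry > tailored
#' selects the recorded start and end dates; missing dates are imputed:
#' start = end − gestational age (273 days when unrecorded), end = start +
#' 273 days, and a record with neither date is anchored on its record date
#' (assumed mid-pregnancy: start = record date − 136).
#'
#' @param records Pregnancies-table rows for one person.
#' @param cfg A [study_config()].
#' @return `data.frame` with `person_id`, `start`, `end`, `colour`,
#'   `source_streams` (comma-joined), `n_records`.
#' @export
reconcile_pregnancies <- function(records, cfg) {
  if (!nrow(records)) return(empty_pregnancy_events())
  if (length(unique(records$person_id)) > 1L)
    stop("reconcile_pregnancies expects records of a single person", call. = FALSE)
  records$anchor <- pregnancy_anchor(records)
  records <- records[order(records$anchor, stream_priority[records$stream]), ]

  groups <- list()
  cur <- records[1, , drop = FALSE]
  cur_end <- cur$recorded_end[1]          # earliest recorded end in the group
  for (i in seq_len(nrow(records))[-1]) {
    r <- records[i, , drop = FALSE]
    split_by_end <- !is.na(cur_end) && r$anchor > cur_end
    if (!split_by_end &&
        as.numeric(r$anchor - cur$anchor[1]) <= GESTATION_DAYS) {
      cur <- rbind(cur, r)
      if (!is.na(r$recorded_end))
        cur_end <- if (is.na(cur_end)) r$recorded_end else min(cur_end, r$recorded_end)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- r
      cur_end <- r$recorded_end
    }
  }
  groups[[length(groups) + 1L]] <- cur

  do.call(rbind, c(lapply(groups, reconcile_group), list(make.row.names = FALSE)))
}

reconcile_group <- function(g) {
  g <- g[order(stream_priority[g$stream]), ]
  s_rec <- g[!is.na(g$recorded_start), , drop = FALSE]
  e_rec <- g[!is.na(g$recorded_end), , drop = FALSE]
  start_recorded <- nrow(s_rec) > 0L
  end_recorded <- nrow(e_rec) > 0L
  if (start_recorded && end_recorded) {
    colour <- "green"
    start <- s_rec$recorded_start[1]
    end <- e_rec$recorded_end[1]
    if (start >= end) {   # cross-stream inconsistency: trust the end record
      colour <- "yellow"
      gest <- e_rec$gestational_age_days[1]
      start <- end - (if (is.na(gest)) GESTATION_DAYS else gest)
    }
  } else if (end_recorded) {
    colour <- "yellow"
    end <- e_rec$recorded_end[1]
    gest <- e_rec$gestational_age_days[1]
    start <- end - (if (is.na(gest)) GESTATION_DAYS else gest)
  } else if (start_recorded) {
    colour <- "blue"
    start <- s_rec$recorded_start[1]
    end <- start + GESTATION_DAYS
  } else {
    colour <- "red"
    start <- g$record_date[1] - 136L
    end <- start + GESTATION_DAYS
  }
  data.frame(person_id = g$person_id[1], start = start, end = end,
             colour = colour,
             source_streams = paste(sort(unique(g$stream)), collapse = ","),
             n_records = nrow(g))
}

empty_pregnancy_events <- function() {
  data.frame(person_id = character(), start = as.Date(character()),
             end = as.Date(character()), colour = character(),
             source_streams = character(), n_records = integer())
}

#' Reconcile pregnancies for every person in a table
#' @param pregnancies A pregnancies table.
#' @param cfg A [study_config()].
#' @return Row-bound output of [reconcile_pregnancies()] per person.
#' @export
reconcile_all_pregnancies <- function(pregnancies, cfg) {
  if (!nrow(pregnancies)) return(empty_pregnancy_events())
  pieces <- lapply(split(pregnancies, pregnancies$person_id),
                   reconcile_pregnancies, cfg = cfg)
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

#' Filter pregnancy events by certainty colour
#'
#' The main analysis keeps green and yellow (recorded end date); the
#' sensitivity analysis adds red.
#'
#' @param events Reconciled pregnancy events.
#' @param allowed Character vector of admitted colours.
#' @return The subset, order preserved.
#' @export
filter_by_colour <- function(events, allowed = c("green", "yellow")) {
  events[events$colour %in% allowed, , drop = FALSE]
}

#' Detect retinoid exposure overlapping a pregnancy
#'
#' Two outcome kinds: a pregnancy whose start falls inside a retinoid episode
#' extended by the teratogenic window (30 days past the episode end, for all
#' three retinoids), and a retinoid record dated inside a pregnancy window.
#' Each unique pregnancy contributes at most one case per kind.
#'
#' @param pregnancies Reconciled (and colour-filtered) pregnancy events.
#' @param episodes Retinoid episodes.
#' @param drugs Drugs table (retinoid record dates for the second kind).
#' @param cfg A [study_config()].
#' @return `data.frame` with `person_id`, `overlap_kind`, `overlap_date`,
#'   `pregnancy_start`, `drug_class`.
#' @export
detect_overlap <- function(pregnancies, episodes, drugs, cfg) {
  empty <- data.frame(person_id = character(), overlap_kind = character(),
                      overlap_date = as.Date(character()),
                      pregnancy_start = as.Date(character()),
                      drug_class = character())
  if (!nrow(pregnancies)) return(empty)
  drugs <- prioritise_dispensing(drugs)
  drugs$drug_class <- atc_to_class(drugs$atc_code, cfg)
  rdrugs <- drugs[drugs$drug_class %in% retinoid_classes(cfg), , drop = FALSE]
  eps <- episodes[episodes$drug_class %in% retinoid_classes(cfg), , drop = FALSE]

  out <- list()
  ext <- cfg$teratogenic_extension_days
  for (i in seq_len(nrow(pregnancies))) {
    p <- pregnancies[i, ]
    pe <- eps[eps$person_id == p$person_id, , drop = FALSE]
    hit <- which(p$start >= pe$start & p$start <= pe$end + ext)
    if (length(hit)) {
      j <- hit[order(pe$start[hit])][1]
      out[[length(out) + 1L]] <- data.frame(
        person_id = p$person_id,
        overlap_kind = "pregnancy_started_during_treatment",
        overlap_date = p$start, pregnancy_start = p$start,
        drug_class = pe$drug_class[j])
    }
    pd <- rdrugs[rdrugs$person_id == p$person_id, , drop = FALSE]
    hit <- which(pd$record_date >= p$start & pd$record_date <= p$end)
    if (length(hit)) {
      j <- hit[order(pd$record_date[hit])][1]   # first record in the pregnancy
      out[[length(out) + 1L]] <- data.frame(
        person_id = p$person_id,
        overlap_kind = "retinoid_started_during_pregnancy",
        overlap_date = pd$record_date[j], pregnancy_start = p$start,
        drug_class = pd$drug_class[j])
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pre/post rate comparison per 1,000 retinoid users
#'
#' Rates are 1,000 x cases / users in each period; the rate difference is
#' post minus pre with a 99% normal-approximation (Wald, Poisson-count)
#' confidence interval. Counts under the small-cell threshold are flagged for
#' masked display; values remain exact for computation.
#'
#' @param cases_pre,users_pre,cases_post,users_post Non-negative counts;
#'   `users_*` must be positive.
#' @param cfg A [study_config()] (for the small-cell threshold).
#' @return One-row `data.frame`: rates, rate difference, CI bounds, masking
#'   flags.
#' @examples
#' cfg <- study_config()
#' pregnancy_rates(88, 117247, 15, 36055, cfg)  # 0.75 -> 0.42, RD -0.33
#' @export
pregnancy_rates <- function(cases_pre, users_pre, cases_post, users_post, cfg) {
  if (users_pre <= 0 || users_post <= 0)
    stop("user counts must be positive", call. = FALSE)
  rate_pre <- 1000 * cases_pre / users_pre
  rate_post <- 1000 * cases_post / users_post
  rd <- rate_post - rate_pre
  se <- 1000 * sqrt(cases_pre / users_pre^2 + cases_post / users_post^2)
  z <- stats::qnorm(0.995)
  data.frame(cases_pre = cases_pre, users_pre = users_pre, rate_pre = rate_pre,
             cases_post = cases_post, users_post = users_post,
             rate_post = rate_post, rate_difference = rd,
             rd_ci99_low = rd - z * se, rd_ci99_high = rd + z * se,
             mask_pre = cases_pre > 0 & cases_pre < cfg$small_cell_threshold,
             mask_post = cases_post > 0 & cases_post < cfg$small_cell_threshold)
}
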