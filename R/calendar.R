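# Calendar arithmetic shared by every stage. Dates are whole days; months
# are indexed 0, 1, 2, ... from the origin month (study start by default).

#' Month index of a date relative to an origin
#'
#' Index 0 is any day of the origin's calendar month; the index increases by
#' one per calendar month regardless of month length.
#'
#' @param d Date vector.
#' @param origin Single Date giving the origin month.
#' @return Integer vector of month offsets.
#' @examples
#' month_index(as.Date("2010-12-31"), as.Date("2010-01-01"))  # 11
#' @export
month_index <- function(d, origin) {
  d <- as.Date(d)
  origin <- as.Date(origin)
  dl <- as.POSIXlt(d)
  ol <- as.POSIXlt(origin)
  idx <- 12L * (dl$year - ol$year) + (dl$mon - ol$mon)
  if (any(idx < 0L, na.rm = TRUE))
    stop("date precedes the origin month", call. = FALSE)
  as.integer(idx)
}

#' First day of the month holding a given month index
#'
#' Inverse of [month_index()] up to truncation to the month start.
#'
#' @param i Integer month index vector.
#' @param origin Single Date giving the origin month.
#' @return Date vector of month starts.
#' @export
month_index_start <- function(i, origin) {
  ol <- as.POSIXlt(as.Date(origin))
  m <- ol$mon + as.integer(i)
  res <- as.Date(sprintf("%04d-%02d-01", ol$year + 1900L + m %/% 12L, m %% 12L + 1L))
  res
}

#' Last day of the month holding a given month index
#' @inheritParams month_index_start
#' @return Date vector of month ends.
#' @export
month_index_end <- function(i, origin) {
  month_index_start(as.integer(i) + 1L, origin) - 1L
}

#' Calendar month-of-year (1-12) of a month index
#' @inheritParams month_index_start
#' @return Integer vector in 1..12.
#' @export
month_of_year <- function(i, origin) {
  ol <- as.POSIXlt(as.Date(origin))
  as.integer((ol$mon + as.integer(i)) %% 12L + 1L)
}

#' Whole-year (birthday-based) age on a date
#'
#' @param birth_date,on Date vectors (recycled).
#' @return Integer ages: the number of completed years of life.
#' @export
age_on <- function(birth_date, on) {
  b <- as.POSIXlt(as.Date(birth_date))
  d <- as.POSIXlt(as.Date(on))
  age <- d$year - b$year
  before_birthday <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  as.integer(age - before_birthday)
}

#' Study-population membership for a person-month
#'
#' A person contributes the month iff recorded female, observed at least one
#' day of the month, and aged within the childbearing band at the month
#' start (whole-year age).
#'
#' @param persons Persons table (see [read_cdm_table()]).
#' @param month Integer month index (single value) relative to
#'   `cfg$study_start`.
#' @param cfg A [study_config()].
#' @return Logical vector along the rows of `persons`.
#' @export
in_study_population <- function(persons, month, cfg) {
  m_start <- month_index_start(month, cfg$study_start)
  m_end <- month_index_end(month, cfg$study_start)
  age <- age_on(persons$birth_date, m_start)
  persons$sex == "F" &
    persons$obs_start <= m_end &
    persons$obs_end >= m_start &
    age >= cfg$age_min & age <= cfg$age_max
}

#' Age band label used for stratified reporting
#'
#' Bands follow the study's reporting table: 12-<21, 21-<31, 31-<41, 41-55.
#'
#' @param age Integer age vector.
#' @return Character band labels; `NA` outside 12-55.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(12, 21, 31, 41, 56), right = FALSE,
      labels = c("12-<21", "21-<31", "31-<41", "41-55")) |> as.character()
}

#' Number of analysis months in the study period
#' @param cfg A [study_config()].
#' @return Integer count of calendar months from study start to study end.
#' @export
n_study_months <- function(cfg) {
  month_index(cfg$study_end, cfg$study_start) + 1L
}
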