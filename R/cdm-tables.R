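# Simplified common-data-model tables: four CSV schemas with ISO-8601 dates.
# Readers validate row-level invariants and report offending rows by number,
# so a malformed extract fails loudly at the boundary instead of deep in the
# analysis.

cdm_schemas <- list(
  persons = list(
    columns = c(person_id = "character", sex = "character",
                birth_date = "Date", obs_start = "Date", obs_end = "Date")
  ),
  drugs = list(
    columns = c(person_id = "character", atc_code = "character",
                record_date = "Date", record_type = "character",
                days_supply = "integer")
  ),
  events = list(
    columns = c(person_id = "character", event_date = "Date",
                event_kind = "character", event_code = "character")
  ),
  pregnancies = list(
    columns = c(person_id = "character", stream = "character",
                record_date = "Date", recorded_start = "Date",
                recorded_end = "Date", gestational_age_days = "integer")
  )
)

pregnancy_streams <- c("birth_registry", "admin_diagnosis", "eurocat", "tailored")
event_kinds <- c("adr_diagnosis", "pregnancy_test", "other")

parse_iso_date <- function(x, col, allow_na = FALSE) {
  x[x == ""] <- NA_character_
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("column '%s': malformed date at row(s) %s", col,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  if (!allow_na && anyNA(out)) {
    bad <- which(is.na(out))
    stop(sprintf("column '%s': missing date at row(s) %s", col,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out
}

fail_rows <- function(cond, msg) {
  bad <- which(cond)
  if (length(bad))
    stop(sprintf("%s at row(s) %s", msg,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
}

#' Read a CDM table from CSV
#'
#' Parses and validates one of the four study tables. Dates must be
#' ISO-8601 (`YYYY-MM-DD`). Rows violating a type invariant abort the read
#' with a message naming the offending column and row numbers.
#'
#' @param path CSV file path.
#' @param table_kind One of `"persons"`, `"drugs"`, `"events"`,
#'   `"pregnancies"`.
#' @return A validated `data.frame` with typed columns.
#' @export
read_cdm_table <- function(path, table_kind) {
  table_kind <- match.arg(table_kind, names(cdm_schemas))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  schema <- cdm_schemas[[table_kind]]$columns
  missing <- setdiff(names(schema), names(raw))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", table_kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop(sprintf("%s: unknown column(s) %s", table_kind,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  df <- raw[names(schema)]
  optional_date <- c("recorded_start", "recorded_end")
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      Date = parse_iso_date(raw[[col]], col, allow_na = col %in% optional_date),
      integer = {
        x <- raw[[col]]
        x[x == ""] <- NA_character_
        out <- suppressWarnings(as.integer(x))
        fail_rows(is.na(out) & !is.na(x),
                  sprintf("column '%s': not an integer", col))
        out
      },
      raw[[col]]
    )
  }
  validate_cdm_table(df, table_kind)
}

#' @rdname read_cdm_table
#' @param df A table previously produced by [read_cdm_table()] or the
#'   synthetic generator.
#' @export
write_cdm_table <- function(df, path, table_kind) {
  table_kind <- match.arg(table_kind, names(cdm_schemas))
  df <- validate_cdm_table(df, table_kind)
  out <- df
  for (col in names(out))
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a CDM table against its row-level invariants
#' @inheritParams write_cdm_table
#' @return The table, invisibly coerced to canonical column order.
#' @export
validate_cdm_table <- function(df, table_kind) {
  table_kind <- match.arg(table_kind, names(cdm_schemas))
  schema <- cdm_schemas[[table_kind]]$columns
  stopifnot(all(names(schema) %in% names(df)))
  df <- df[names(schema)]
  switch(table_kind,
    persons = {
      fail_rows(!df$sex %in% c("F", "M"), "column 'sex': must be F or M")
      fail_rows(df$obs_start > df$obs_end, "obs_start after obs_end")
      fail_rows(df$birth_date > df$obs_start, "birth_date after obs_start")
    },
    drugs = {
      fail_rows(is.na(df$atc_code) | df$atc_code == "",
                "column 'atc_code': empty")
      fail_rows(!df$record_type %in% c("prescription", "dispensing"),
                "column 'record_type': must be prescription or dispensing")
      fail_rows(!is.na(df$days_supply) & df$days_supply <= 0L,
                "column 'days_supply': must be positive when present")
    },
    events = {
      fail_rows(!df$event_kind %in% event_kinds,
                "column 'event_kind': outside vocabulary")
    },
    pregnancies = {
      fail_rows(!df$stream %in% pregnancy_streams,
                "column 'stream': unknown stream")
      fail_rows(is.na(df$record_date), "column 'record_date': missing")
      both <- !is.na(df$recorded_start) & !is.na(df$recorded_end)
      fail_rows(both & df$recorded_start >= df$recorded_end,
                "recorded_start not before recorded_end")
      fail_rows(!is.na(df$gestational_age_days) & df$gestational_age_days < 0L,
                "column 'gestational_age_days': negative")
    }
  )
  df
}

#' Prioritise dispensings over prescriptions
#'
#' When a prescription and a dispensing exist for the same person, ATC code
#' and date, the dispensing is kept (the dispensing date reflects actual
#' supply).
#'
#' @param drugs A drugs table.
#' @return The drugs table with shadowed prescriptions dropped.
#' @export
prioritise_dispensing <- function(drugs) {
  key <- paste(drugs$person_id, drugs$atc_code, drugs$record_date)
  disp <- key[drugs$record_type == "dispensing"]
  drop <- drugs$record_type == "prescription" & key %in% disp
  drugs[!drop, , drop = FALSE]
}

#' Map an ATC code to an analysis drug class
#'
#' @param atc Character vector of ATC codes.
#' @param cfg A [study_config()].
#' @return Character vector: one of the three retinoid classes,
#'   `"contraceptive_hormonal"`, `"contraceptive_user_independent"`,
#'   `"folic_acid"`, `"antidepressant"`, or `NA` for anything else.
#' @export
atc_to_class <- function(atc, cfg) {
  out <- rep(NA_character_, length(atc))
  for (cls in names(cfg$retinoid_atc))
    out[atc == cfg$retinoid_atc[[cls]]] <- cls
  out[startsWith(atc, cfg$user_independent_atc_prefix)] <-
    "contraceptive_user_independent"
  out[startsWith(atc, cfg$hormonal_atc_prefix)] <- "contraceptive_hormonal"
  out[atc == cfg$folic_atc] <- "folic_acid"
  out[startsWith(atc, cfg$antidepressant_atc_prefix)] <- "antidepressant"
  out
}

retinoid_classes <- function(cfg) names(cfg$retinoid_atc)

# Union of closed day-intervals given as a two-column data.frame; returns the
# merged intervals sorted by start. Adjacent (end + 1 == start) intervals are
# coalesced.
merge_day_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (!length(start))
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- oute <- list()
  k <- 0L
  for (i in seq_along(start)[-1]) {
    if (as.numeric(start[i] - me) <= 1) {
      me <- max(me, end[i])
    } else {
      k <- k + 1L; outs[[k]] <- ms; oute[[k]] <- me
      ms <- start[i]; me <- end[i]
    }
  }
  k <- k + 1L; outs[[k]] <- ms; oute[[k]] <- me
  data.frame(start = as.Date(unlist(lapply(outs, format))),
             end = as.Date(unlist(lapply(oute, format))))
}
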