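#' Study configuration
#'
#' Bundle of the study window, age band, episode/discontinuation gap rules,
#' lookback and reason windows, and the country-specific risk-minimisation
#' measure (RMM) implementation windows that drive the interrupted
#' time-series gap exclusion.
#'
#' All intervals in the package are closed `[start, end]` on whole calendar
#' days; every window parameter below is a day count.
#'
#' @param study_start,study_end Date bounds of the study period.
#' @param covid_censor_end Optional Date; when set, analyses are censored
#'   after this date (COVID-19 sensitivity analysis).
#' @param rmm_country One of `"DK"`, `"IT"`, `"NL"`, `"ES"`; selects the
#'   promulgation-to-implementation window excluded from the ITS.
#' @param age_min,age_max Whole-year age band for childbearing potential.
#' @param episode_gap_days Permissible gap: records whose coverage intervals
#'   are separated by fewer than this many days are merged into one episode.
#' @param discontinuation_gap_days Days without a same-class record after the
#'   last record before an episode counts as discontinued (30 in the
#'   sensitivity analysis).
#' @param lookback_days Observation required before a month for a person to be
#'   evaluable for incidence, and the window screened for prior use.
#' @param teratogenic_extension_days Days added to a retinoid episode end when
#'   screening for pregnancy onset during exposure.
#' @param reason_window_days Days after a discontinuation screened for the
#'   discontinuation reason (pregnancy, folic acid, ADR).
#' @param small_cell_threshold Counts below this are masked in reports.
#' @param default_days_supply Days of supply assumed when a drug record
#'   carries none (the revised programme mandates maximum 30-day supplies).
#' @param device_supply_days Assumed coverage of a user-independent
#'   contraceptive device (intra-uterine device or implant) record.
#' @param include_hormonal_coverage Logical; when `TRUE` hormonal episodes
#'   count as contraception coverage on their own (permissive mode). Default
#'   `FALSE`: only user-independent methods qualify, because barrier methods
#'   (required alongside hormonal ones) are over-the-counter and invisible to
#'   electronic health databases.
#' @param allowed_colours Pregnancy certainty colours retained in the main
#'   analysis; the sensitivity analysis adds `"red"`.
#' @param folic_atc ATC code marking a pregnancy-wish proxy.
#' @param antidepressant_atc_prefix ATC prefix used as depression-ADR proxy.
#' @param retinoid_atc Named character vector mapping retinoid drug-class
#'   names to ATC codes.
#' @param hormonal_atc_prefix,user_independent_atc_prefix ATC prefixes
#'   classifying contraceptive records.
#' @param adr_codes Character vector of diagnosis codes counted as
#'   retinoid-associated adverse drug reactions (source-specific; supplied by
#'   configuration, not hard-coded).
#'
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(study_start = as.Date("2010-01-01"),
                         study_end = as.Date("2020-12-31"),
                         covid_censor_end = NULL,
                         rmm_country = "ES",
                         age_min = 12L,
                         age_max = 55L,
                         episode_gap_days = 30L,
                         discontinuation_gap_days = 90L,
                         lookback_days = 365L,
                         teratogenic_extension_days = 30L,
                         reason_window_days = 90L,
                         small_cell_threshold = 5L,
                         default_days_supply = 30L,
                         device_supply_days = 1095L,
                         include_hormonal_coverage = FALSE,
                         allowed_colours = c("green", "yellow"),
                         folic_atc = "B03BB01",
                         antidepressant_atc_prefix = "N06A",
                         retinoid_atc = c(isotretinoin = "D10BA01",
                                          acitretin = "D05BB02",
                                          alitretinoin = "D11AH04"),
                         hormonal_atc_prefix = "G03A",
                         user_independent_atc_prefix = "G02B",
                         adr_codes = c("ADR_RETINOID")) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (!is.null(covid_censor_end)) covid_censor_end <- as.Date(covid_censor_end)
  rmm_country <- match.arg(rmm_country, c("DK", "IT", "NL", "ES"))

  cfg <- structure(list(
    study_start = study_start,
    study_end = study_end,
    covid_censor_end = covid_censor_end,
    rmm_country = rmm_country,
    rmm_windows = rmm_implementation_windows(),
    age_min = as.integer(age_min),
    age_max = as.integer(age_max),
    episode_gap_days = as.integer(episode_gap_days),
    discontinuation_gap_days = as.integer(discontinuation_gap_days),
    lookback_days = as.integer(lookback_days),
    teratogenic_extension_days = as.integer(teratogenic_extension_days),
    reason_window_days = as.integer(reason_window_days),
    small_cell_threshold = as.integer(small_cell_threshold),
    default_days_supply = as.integer(default_days_supply),
    device_supply_days = as.integer(device_supply_days),
    include_hormonal_coverage = isTRUE(include_hormonal_coverage),
    allowed_colours = allowed_colours,
    folic_atc = folic_atc,
    antidepressant_atc_prefix = antidepressant_atc_prefix,
    retinoid_atc = retinoid_atc,
    hormonal_atc_prefix = hormonal_atc_prefix,
    user_independent_atc_prefix = user_independent_atc_prefix,
    adr_codes = adr_codes
  ), class = "study_config")
  validate_study_config(cfg)
  cfg
}

#' National 2018 RMM implementation windows
#'
#' Promulgation-to-implementation dates of the revised pregnancy prevention
#' programme in the four study countries. The window is excluded from the
#' interrupted time series; the intervention is anchored at its end.
#'
#' @return Named list of length-2 Date vectors `c(promulgation, implementation)`.
#' @export
rmm_implementation_windows <- function() {
  list(
    DK = as.Date(c("2018-07-16", "2018-10-11")),
    IT = as.Date(c("2018-08-08", "2018-10-02")),
    NL = as.Date(c("2018-08-10", "2018-12-12")),
    ES = as.Date(c("2018-07-24", "2018-12-01"))
  )
}

#' @rdname study_config
#' @param cfg A `study_config` object.
#' @return `rmm_gap()`: the selected country's `c(promulgation, implementation)`
#'   Date pair.
#' @export
rmm_gap <- function(cfg) {
  cfg$rmm_windows[[cfg$rmm_country]]
}

validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg$study_start, "Date"), inherits(cfg$study_end, "Date"))
  if (cfg$study_start >= cfg$study_end)
    stop("study_start must precede study_end", call. = FALSE)
  win <- c(cfg$episode_gap_days, cfg$discontinuation_gap_days,
           cfg$lookback_days, cfg$teratogenic_extension_days,
           cfg$reason_window_days, cfg$default_days_supply,
           cfg$device_supply_days)
  if (any(win <= 0)) stop("all window lengths must be positive", call. = FALSE)
  if (cfg$age_min >= cfg$age_max) stop("age_min must be below age_max", call. = FALSE)
  gap <- rmm_gap(cfg)
  if (gap[1] < cfg$study_start || gap[2] > cfg$study_end)
    stop("RMM implementation window must lie inside the study period", call. = FALSE)
  bad <- setdiff(cfg$allowed_colours, c("green", "yellow", "blue", "red"))
  if (length(bad)) stop("unknown pregnancy colour: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  invisible(cfg)
}

#' Read or write a study configuration as YAML
#'
#' Only scalar fields are serialised; the RMM window table is rebuilt from the
#' country code so the file stays small and human-editable.
#'
#' @param path File path.
#' @param cfg A `study_config`.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  date_fields <- c("study_start", "study_end", "covid_censor_end")
  for (f in intersect(date_fields, names(raw))) {
    if (!is.null(raw[[f]])) raw[[f]] <- as.Date(raw[[f]])
  }
  if (!is.null(raw$retinoid_atc)) raw$retinoid_atc <- unlist(raw$retinoid_atc)
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(cfg, path) {
  keep <- setdiff(names(cfg), "rmm_windows")
  out <- cfg[keep]
  out <- lapply(out, function(x) if (inherits(x, "Date")) format(x) else x)
  out$retinoid_atc <- as.list(cfg$retinoid_atc)
  yaml::write_yaml(out, path)
  invisible(path)
}
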