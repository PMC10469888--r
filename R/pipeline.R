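# Stage orchestration: simulate -> episodes -> pregnancy -> measures -> its
# -> report, every stage a pure function of the CSVs in the working
# directory plus the configuration, so reruns are hash-stable. The manifest
# lists every output file with its MD5 content hash.

pipeline_stages <- c("simulate", "episodes", "pregnancy", "measures",
                     "its", "report")

#' Read a pipeline configuration file
#'
#' YAML with two optional top-level keys: `scenario` (fields of
#' [simulation_scenario()]) and `study` (fields of [study_config()]).
#'
#' @param path YAML file path.
#' @return List with elements `scenario` and `cfg`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- if (is.null(raw$study)) study_config() else {
    for (f in c("study_start", "study_end", "covid_censor_end"))
      if (!is.null(raw$study[[f]])) raw$study[[f]] <- as.Date(raw$study[[f]])
    do.call(study_config, raw$study)
  }
  scenario <- if (is.null(raw$scenario)) simulation_scenario() else
    do.call(simulation_scenario, raw$scenario)
  list(scenario = scenario, cfg = cfg)
}

read_stage_tables <- function(dir) {
  list(persons = read_cdm_table(file.path(dir, "persons.csv"), "persons"),
       drugs = read_cdm_table(file.path(dir, "drugs.csv"), "drugs"),
       events = read_cdm_table(file.path(dir, "events.csv"), "events"),
       pregnancies = read_cdm_table(file.path(dir, "pregnancies.csv"),
                                    "pregnancies"))
}

write_result_csv <- function(df, path) {
  for (col in names(df))
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order inside `out_dir`; every stage reads
#' the CSVs earlier stages wrote, so stages can be rerun individually.
#' Failures abort with a message naming the stage. Returns a manifest of all
#' files written with MD5 content hashes; identical configuration and seed
#' reproduce identical hashes.
#'
#' @param out_dir Working/output directory.
#' @param scenario A [simulation_scenario()]; `seed` overrides its seed.
#' @param cfg A [study_config()].
#' @param config_path Optional YAML (see [read_pipeline_config()]) taking the
#'   place of `scenario`/`cfg`.
#' @param stages Subset of
#'   `c("simulate","episodes","pregnancy","measures","its","report")`.
#' @param seed Optional integer overriding the scenario seed.
#' @return Invisibly, a `data.frame` manifest (`stage`, `file`, `md5`),
#'   also written to `manifest.csv`, with attached `warnings`.
#' @export
run_pipeline <- function(out_dir, scenario = simulation_scenario(),
                         cfg = study_config(), config_path = NULL,
                         stages = pipeline_stages, seed = NULL) {
  if (!is.null(config_path)) {
    pc <- read_pipeline_config(config_path)
    scenario <- pc$scenario; cfg <- pc$cfg
  }
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character())
  warnings <- character()
  note <- function(stage, files) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files))))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sim <- simulate_cdm(scenario, cfg)
    write_simulation(sim, out_dir)
    note("simulate", file.path(out_dir,
      c("persons.csv", "drugs.csv", "events.csv", "pregnancies.csv",
        "ledger_episodes.csv", "ledger_pregnancies.csv", "monthly_truth.csv")))
  })

  if ("episodes" %in% stages) run_stage("episodes", function() {
    tb <- read_stage_tables(out_dir)
    eps <- build_all_episodes(tb$drugs, cfg)
    eps <- flag_discontinuation(eps, tb$drugs, tb$persons, cfg)
    if (any(!eps$assessable))
      warnings <<- c(warnings, sprintf("%d episode(s) not assessable",
                                       sum(!eps$assessable)))
    note("episodes", write_result_csv(eps, file.path(out_dir, "episodes.csv")))
  })

  if ("pregnancy" %in% stages) run_stage("pregnancy", function() {
    tb <- read_stage_tables(out_dir)
    eps <- read_episodes_csv(file.path(out_dir, "episodes.csv"))
    recon <- reconcile_all_pregnancies(tb$pregnancies, cfg)
    note("pregnancy", write_result_csv(
      recon, file.path(out_dir, "pregnancies_reconciled.csv")))
    kept <- filter_by_colour(recon, cfg$allowed_colours)
    retinoid_eps <- eps[eps$drug_class %in% retinoid_classes(cfg), ]
    exposed <- detect_overlap(kept, retinoid_eps, tb$drugs, cfg)
    note("pregnancy", write_result_csv(
      exposed, file.path(out_dir, "exposed_pregnancies.csv")))
    eps <- classify_discontinuation(eps, tb$events, tb$drugs, kept, cfg)
    note("pregnancy", write_result_csv(eps, file.path(out_dir, "episodes.csv")))
  })

  if ("measures" %in% stages) run_stage("measures", function() {
    tb <- read_stage_tables(out_dir)
    eps <- read_episodes_csv(file.path(out_dir, "episodes.csv"))
    retinoid_eps <- eps[eps$drug_class %in% retinoid_classes(cfg), ]
    contra_eps <- eps[startsWith(eps$drug_class, "contraceptive"), ]
    cov <- contraception_coverage(contra_eps, cfg)
    series <- rbind(
      monthly_incidence(tb$drugs, tb$persons, cfg),
      monthly_prevalence(retinoid_eps, tb$persons, cfg),
      discontinuation_rate(retinoid_eps, cfg),
      contraception_proportions(retinoid_eps, cov, contra_eps, cfg),
      pregnancy_testing_proportions(tb$events, retinoid_eps, tb$persons, cfg))
    note("measures", write_result_csv(series, file.path(out_dir, "series.csv")))
  })

  if ("its" %in% stages) run_stage("its", function() {
    series <- utils::read.csv(file.path(out_dir, "series.csv"))
    fit_one <- function(nm) {
      s <- series[series$series_name == nm, ]
      tryCatch(its_tidy(fit_its(s, cfg)), error = function(e) {
        warnings <<- c(warnings, sprintf("ITS refused for '%s': %s", nm,
                                         conditionMessage(e)))
        NULL
      })
    }
    rows <- Filter(Negate(is.null), lapply(
      c("incidence", "prevalence", "discontinuation",
        "contraception_covered", "contraception_prior90"), fit_one))
    res <- if (length(rows)) do.call(rbind, rows) else
      data.frame(series_name = character())
    note("its", write_result_csv(res, file.path(out_dir, "its_results.csv")))
  })

  if ("report" %in% stages) run_stage("report", function() {
    report <- pipeline_report(out_dir, cfg)
    note("report", c(file.path(out_dir, "report_rates.csv"),
                     file.path(out_dir, "report.txt")))
  })

  write_result_csv(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "warnings") <- warnings
  invisible(manifest)
}

read_episodes_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  for (col in c("start", "end", "last_record_date", "discontinuation_date"))
    if (col %in% names(df)) df[[col]] <- as.Date(df[[col]])
  df$n_records <- as.integer(df$n_records)
  for (col in c("assessable", "discontinued"))
    if (col %in% names(df)) df[[col]] <- df[[col]] == "TRUE"
  df
}

#' Pre/post exposed-pregnancy rate report
#'
#' Aggregates exposed-pregnancy cases and prevalent retinoid users into the
#' pre-intervention period (before the RMM promulgation) and post period
#' (from the implementation date), and computes rates per 1,000 users with
#' the rate difference, per overlap kind. The human-readable report masks
#' small cells; the CSV keeps exact counts.
#'
#' @param out_dir Pipeline directory holding `episodes.csv` and
#'   `exposed_pregnancies.csv`.
#' @param cfg A [study_config()].
#' @return The rate-comparison `data.frame`, invisibly.
#' @export
pipeline_report <- function(out_dir, cfg) {
  eps <- read_episodes_csv(file.path(out_dir, "episodes.csv"))
  eps <- eps[eps$drug_class %in% retinoid_classes(cfg), ]
  exposed <- utils::read.csv(file.path(out_dir, "exposed_pregnancies.csv"))
  exposed$overlap_date <- as.Date(exposed$overlap_date)
  gap <- rmm_gap(cfg)
  pre_end <- gap[1] - 1L
  post_start <- gap[2]
  users_in <- function(a, b)
    length(unique(eps$person_id[eps$start <= b & eps$end >= a]))
  users_pre <- users_in(cfg$study_start, pre_end)
  users_post <- users_in(post_start, cfg$study_end)
  rows <- lapply(unique(c("pregnancy_started_during_treatment",
                          "retinoid_started_during_pregnancy")), function(kind) {
    k <- exposed[exposed$overlap_kind == kind, ]
    cbind(overlap_kind = kind, pregnancy_rates(
      sum(k$overlap_date <= pre_end), max(users_pre, 1L),
      sum(k$overlap_date >= post_start), max(users_post, 1L), cfg))
  })
  rates <- do.call(rbind, rows)
  write_result_csv(rates, file.path(out_dir, "report_rates.csv"))

  thr <- cfg$small_cell_threshold
  mask <- function(x) ifelse(x > 0 & x < thr, paste0("<", thr), x)
  lines <- c("Exposed-pregnancy rate comparison (per 1,000 prevalent users)",
             sprintf("pre period: %s to %s (%d users)", cfg$study_start,
                     pre_end, users_pre),
             sprintf("post period: %s to %s (%d users)", post_start,
                     cfg$study_end, users_post))
  for (i in seq_len(nrow(rates))) {
    r <- rates[i, ]
    lines <- c(lines, sprintf(
      "%s: pre %s/%d (%.2f) post %s/%d (%.2f) RD %.2f (99%% CI %.2f to %.2f)",
      r$overlap_kind, mask(r$cases_pre), r$users_pre, r$rate_pre,
      mask(r$cases_post), r$users_post, r$rate_post, r$rate_difference,
      r$rd_ci99_low, r$rd_ci99_high))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(rates)
}
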