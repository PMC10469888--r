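#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# One scenario plays the role of a mid-sized national database: 20,000
# females observed 2010-2020, retinoid initiations at 0.2 new users per
# 1,000 person-months with a 30% mid-July trough, null intervention effects
# at the Spanish implementation date (2018-12), pregnancies at 60 per 1,000
# person-years reported through four streams of differing completeness.

library(rmmits)

out_dir <- "results/pipeline"
cfg <- study_config()
scenario <- simulation_scenario(n_persons = 20000L, seed = 101L)

message("simulating ", scenario$n_persons, " persons over ",
        n_study_months(cfg), " months ...")
run_pipeline(out_dir, scenario, cfg, stages = "simulate")
write_study_config(cfg, file.path(out_dir, "study_config.yaml"))

persons <- read_cdm_table(file.path(out_dir, "persons.csv"), "persons")
drugs <- read_cdm_table(file.path(out_dir, "drugs.csv"), "drugs")
led <- read.csv(file.path(out_dir, "ledger_episodes.csv"))
ledp <- read.csv(file.path(out_dir, "ledger_pregnancies.csv"))

cat(sprintf("cohort: %d persons (%d female), %d drug records\n",
            nrow(persons), sum(persons$sex == "F"), nrow(drugs)))
cat(sprintf("truth: %d retinoid episodes (%d discontinued), %d pregnancies\n",
            nrow(led), sum(led$discontinued == "TRUE"), nrow(ledp)))
cat("pregnancy certainty colours in truth:\n")
print(table(ledp$colour))
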