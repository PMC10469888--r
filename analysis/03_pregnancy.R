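#!/usr/bin/env Rscript
# Stage 3: reconcile pregnancy source records into colour-coded pregnancy
# events, detect retinoid-pregnancy overlap (with the 30-day teratogenic
# extension), and classify discontinuation reasons.

library(rmmits)

out_dir <- "results/pipeline"
cfg <- study_config()
run_pipeline(out_dir, cfg = cfg, stages = "pregnancy")

recon <- read.csv(file.path(out_dir, "pregnancies_reconciled.csv"))
exposed <- read.csv(file.path(out_dir, "exposed_pregnancies.csv"))
eps <- read.csv(file.path(out_dir, "episodes.csv"))
ret <- eps[eps$drug_class %in% names(cfg$retinoid_atc), ]

cat(sprintf("reconciled %d pregnancies; colour distribution:\n", nrow(recon)))
print(round(100 * prop.table(table(recon$colour)), 1))
cat(sprintf("main analysis keeps green+yellow: %d of %d\n",
            sum(recon$colour %in% cfg$allowed_colours), nrow(recon)))
cat("retinoid-pregnancy overlap events:\n")
print(table(exposed$overlap_kind))
disc <- ret[ret$discontinued == "TRUE", ]
cat(sprintf("discontinuation reasons (%d discontinuations):\n", nrow(disc)))
print(round(100 * prop.table(table(disc$reason)), 2))
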