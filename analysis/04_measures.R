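#!/usr/bin/env Rscript
# Stage 4: monthly utilisation series - incidence per 1,000 person-months,
# prevalence per 1,000 persons, quarterly-denominator discontinuation
# proportion, contraception coverage/priming proportions, pregnancy-testing
# proportions.

library(rmmits)

out_dir <- "results/pipeline"
cfg <- study_config()
run_pipeline(out_dir, cfg = cfg, stages = "measures")

series <- read.csv(file.path(out_dir, "series.csv"))
for (nm in unique(series$series_name)) {
  s <- series[series$series_name == nm, ]
  cat(sprintf("%-24s mean %.4f over %d defined months\n", nm,
              mean(s$value, na.rm = TRUE), sum(!is.na(s$value))))
}

# the seasonal signature: incidence by calendar month
inc <- series[series$series_name == "incidence" & !is.na(series$value), ]
moy <- month_of_year(inc$month, cfg$study_start)
by_moy <- tapply(inc$value, moy, mean)
cat("mean incidence by calendar month (per 1,000 PM):\n")
print(round(by_moy, 3))
cat(sprintf("July dip: %.3f vs annual mean %.3f\n",
            by_moy[["7"]], mean(inc$value)))
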