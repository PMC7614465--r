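#!/usr/bin/env Rscript
# Stage 5: collate the headline numbers of stages 2-4 into one JSON report.
# Fails with a clear message if an upstream stage has not been run.

library(iegcoupling)
library(jsonlite)

need <- c("results/coupling/peaks_Arc.csv",
          "results/coupling/peaks_cFos.csv",
          "results/coupling/peaks_EGR1.csv",
          "results/coupling/line_comparisons.csv",
          "results/dynamics/timecourse_ieg_Arc.csv",
          "results/responses/high_ieg_contrasts.csv")
missing <- need[!file.exists(need)]
if (length(missing)) {
  stop("missing upstream outputs (run analysis/01..04 first):\n  ",
       paste(missing, collapse = "\n  "), call. = FALSE)
}

report <- list()
for (line in c("Arc", "cFos", "EGR1")) {
  pk <- read.csv(sprintf("results/coupling/peaks_%s.csv", line))
  report[[paste0("peak_r_", line)]] <- mean(pk$peak_r)
  report[[paste0("peak_lag_h_", line)]] <- mean(pk$peak_lag_h)
}
cmp <- read.csv("results/coupling/line_comparisons.csv")
report$min_between_line_p <- min(cmp$p_value)
hi <- read.csv("results/responses/high_ieg_contrasts.csv")
run <- hi[hi$statistic == "running_onset", ]
report$egr1_high_minus_rest_running_z <-
  mean(run$high_mean[run$line == "EGR1"] - run$rest_mean[run$line == "EGR1"])
grat <- hi[hi$statistic == "grating_onset", ]
report$arc_high_minus_rest_grating_z <-
  mean(grat$high_mean[grat$line == "Arc"] - grat$rest_mean[grat$line == "Arc"])

write_json(report, "results/report.json", auto_unbox = TRUE, digits = NA)
message("report written to results/report.json")
print(unlist(report))
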