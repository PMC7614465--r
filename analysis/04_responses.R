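#!/usr/bin/env Rscript
# Stage 4: functional characterization of high-IEG neurons on the learning
# cohorts: top-10% selection at the first day of condition 3, event-triggered
# population z-scores (running onsets in darkness, drifting-grating onsets,
# visuomotor mismatch), open-loop running/visual-flow correlations, and
# high-vs-rest group contrasts.

library(iegcoupling)

sim <- "results/sim"
out <- "results/responses"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (line in c("Arc", "cFos", "EGR1")) {
  coh <- readRDS(file.path(sim, paste0("learning_", line, ".rds")))
  for (mi in seq_along(coh)) {
    m <- coh[[mi]]
    hi <- select_high_ieg(m$ieg_norm, reference_sessions = c(9, 10))
    zs <- list(
      running_onset = pooled_event_zscores(m, "running_onset",
                                           conditions = c(2, 3))$zscore,
      grating_onset = pooled_event_zscores(m, "grating_onset",
                                           conditions = c(2, 3))$zscore,
      mismatch = pooled_event_zscores(m, "mismatch", conditions = 3)$zscore)
    bc <- behavior_correlations(m)
    zs$r_running <- bc$r_running
    zs$r_flow <- bc$r_flow
    for (stat in names(zs)) {
      gc <- group_contrast(zs[[stat]], hi)
      rows[[length(rows) + 1]] <- data.frame(
        line = line, mouse = mi, statistic = stat,
        n_high = length(hi),
        high_mean = gc$group_mean, high_sem = gc$group_sem,
        rest_mean = gc$rest_mean, rest_sem = gc$rest_sem,
        p_vs_zero = if (is.null(gc$vs_zero)) NA else gc$vs_zero$p_value,
        p_vs_rest = if (is.null(gc$vs_rest)) NA else gc$vs_rest$p_value)
    }
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "high_ieg_contrasts.csv"), row.names = FALSE)

for (stat in unique(tab$statistic)) {
  d <- tab[tab$statistic == stat, ]
  agg <- aggregate(cbind(high_mean, rest_mean) ~ line, d, mean)
  message(sprintf("%-13s  %s", stat, paste(sprintf("%s: high %+.3f rest %+.3f",
                                                   agg$line, agg$high_mean,
                                                   agg$rest_mean),
                                           collapse = " | ")))
}
message("high-IEG contrast table written to ", out)
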