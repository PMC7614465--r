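#!/usr/bin/env Rscript
# Stage 3: expression and activity dynamics across the three learning
# conditions (dark -> first visual exposure -> normal visuomotor coupling).
#
# Per line: per-mouse timecourses of mean activity and mean normalized
# expression, condition-boundary change statistics, the linear activity trend
# over conditions 2-3, and rank-order expression-pattern similarity matrices.

library(iegcoupling)

sim <- "results/sim"
out <- "results/dynamics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (line in c("Arc", "cFos", "EGR1")) {
  coh <- readRDS(file.path(sim, paste0("learning_", line, ".rds")))
  tc_act <- build_timecourse(coh, "activity")
  tc_ieg <- build_timecourse(coh, "ieg")
  write.csv(cbind(line = line, quantity = "activity", tc_act),
            file.path(out, paste0("timecourse_activity_", line, ".csv")),
            row.names = FALSE)
  write.csv(cbind(line = line, quantity = "ieg", tc_ieg),
            file.path(out, paste0("timecourse_ieg_", line, ".csv")),
            row.names = FALSE)

  for (bd in list(c(1, 2), c(2, 3))) {
    ch <- condition_change(tc_ieg, bd)
    message(sprintf(
      "%s expression change condition %d -> %d: %+.4f +/- %.4f (p = %.4f)",
      line, bd[1], bd[2], ch$mean_change, ch$sem_change,
      if (is.null(ch$test)) NA else ch$test$p_value))
  }

  lt <- linear_trend(tc_act, c(2, 3))
  message(sprintf("%s activity trend (cond 2-3): slope %+.3g, R2 = %.3f, p = %.4f",
                  line, lt$slope, lt$r_squared, lt$test$p_value))

  sim_mat <- pattern_similarity(coh)
  write.csv(sim_mat, file.path(out, paste0("similarity_", line, ".csv")),
            row.names = FALSE)
}
message("dynamics tables written to ", out)
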