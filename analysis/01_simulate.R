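#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic cohorts every downstream analysis uses.
#
# Two experiments per reporter line (Arc, c-Fos, EGR1):
#   * a dark-adaptation cohort (4 mice, measurements every 15 min for 6 h,
#     one grating-stimulation block after the baseline measurement), and
#   * a visuomotor-learning cohort (2 mice, 12 sessions over 6 days in three
#     conditions), run at reduced recording length so the whole workflow
#     stays interactive; the session structure is untouched.
# One example mouse is additionally exported as plain CSV/YAML.

library(iegcoupling)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
lines <- c("Arc", "cFos", "EGR1")

for (line in lines) {
  cfg1 <- generator_config(ieg_line = line, n_mice = 4L,
                           n_neurons_per_mouse = 300L)
  coh1 <- simulate_cohort(cfg1, "dark_adapt_fig1", seed = 1000 + match(line, lines),
                          keep_fluor = FALSE)
  saveRDS(coh1, file.path(out, paste0("dark_adapt_", line, ".rds")))

  cfg2 <- generator_config(ieg_line = line, n_mice = 2L,
                           n_neurons_per_mouse = 200L,
                           fig2_segment_s = 120, grating_n_reps = 3L,
                           halt_rate_hz = 0.2, halt_refractory_s = 3)
  coh2 <- simulate_cohort(cfg2, "learning_fig2", seed = 2000 + match(line, lines),
                          keep_fluor = FALSE)
  saveRDS(coh2, file.path(out, paste0("learning_", line, ".rds")))
  message(sprintf("%s: %d + %d mice simulated (%d neurons each)",
                  line, length(coh1), length(coh2),
                  nrow(coh1[[1]]$truth)))
}

export_mouse_dataset(readRDS(file.path(out, "dark_adapt_Arc.rds"))[[1]],
                     file.path(out, "example_mouse_csv"))
message("example mouse exported to ", file.path(out, "example_mouse_csv"))
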