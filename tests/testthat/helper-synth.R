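# Shared fixtures: scaled-down generator configurations and hand-built
# mouse-dataset stubs used across the unit tests.

# Small dark-adaptation cohort (fast; full protocol structure).
fig1_cfg <- function(line = "Arc", n_mice = 2L, n_neurons = 80L, ...) {
  generator_config(n_mice = n_mice, n_neurons_per_mouse = n_neurons,
                   ieg_line = line, ...)
}

# Scaled learning-protocol config: short recordings, 3 grating reps.
fig2_cfg <- function(line = "Arc", n_mice = 1L, n_neurons = 120L, ...) {
  # halts are denser than at full scale so the shortened closed-loop
  # recordings still carry a usable number of mismatch events
  generator_config(n_mice = n_mice, n_neurons_per_mouse = n_neurons,
                   ieg_line = line, fig2_segment_s = 60, grating_n_reps = 3L,
                   halt_rate_hz = 0.2, halt_refractory_s = 3, ...)
}

# Minimal mouse-like object from hand-built dF/F matrices; one segment per
# session, snapshot at each session time.
fake_mouse <- function(dff_list, time_h = seq_along(dff_list) - 1,
                       condition = rep(1L, length(dff_list)),
                       kind = rep("dark", length(dff_list)),
                       ieg_values = NULL) {
  n <- nrow(dff_list[[1]])
  segs <- lapply(seq_along(dff_list), function(k) {
    list(session = k, condition = condition[k], kind = kind[k],
         onset_s = time_h[k] * 3600, duration_s = ncol(dff_list[[k]]) / 10,
         time_h = time_h[k], dff = dff_list[[k]],
         behavior = data.frame(
           time_s = time_h[k] * 3600 + (seq_len(ncol(dff_list[[k]])) - 1) / 10,
           running_speed = 0, visual_flow = 0, stimulus_state = "dark",
           orientation_deg = NA_real_),
         events = data.frame(time_s = numeric(0), kind = character(0),
                             orientation_deg = numeric(0)))
  })
  if (is.null(ieg_values)) ieg_values <- matrix(1, n, length(dff_list))
  raw <- structure(list(values = ieg_values, timepoint_h = time_h,
                        session = seq_along(dff_list),
                        condition = condition, normalized = FALSE),
                   class = "ieg_snapshots")
  norm <- tryCatch(normalize_ieg(raw), error = function(e) raw)
  list(truth = data.frame(neuron = seq_len(n)),
       segments = segs, ieg_raw = raw, ieg_norm = norm,
       cfg = generator_config(n_neurons_per_mouse = n))
}

# Brute-force lagged population correlation: explicit double loop over all
# timepoint pairs, used as the independent oracle.
brute_lagged_correlation <- function(av, at, iv, it, lag_grid) {
  sapply(lag_grid, function(L) {
    rs <- c()
    for (a in seq_along(at)) for (i in seq_along(it)) {
      if (abs((it[i] - at[a]) - L) < 0.125 - 1e-9 ||
          isTRUE(all.equal(it[i] - at[a], L))) {
        rs <- c(rs, stats::cor(av[, a], iv[, i]))
      }
    }
    if (length(rs)) mean(rs) else NA_real_
  })
}
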