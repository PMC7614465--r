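#' Simulate behavior for every segment of a schedule
#'
#' Locomotion is a two-state (rest/run) Markov process with exponential dwell
#' times; running speed within a bout is a per-bout target speed plus AR(1)
#' jitter, rectified at zero. Visual flow follows the segment kind:
#' closed-loop flow equals `closed_loop_gain * running_speed` except during
#' inserted 1-s halts (flow 0); open-loop segments replay, sample for sample,
#' the flow of the preceding closed-loop segment of the same session; dark
#' and grating segments carry zero flow. Halts are inserted as a thinned
#' Poisson process (`halt_rate_hz`), only while the mouse runs faster than
#' `run_threshold`, with a refractory gap of at least `halt_refractory_s`.
#'
#' @param schedule an [build_schedule()] object.
#' @param cfg an [generator_config()] object.
#' @param seed integer seed.
#' @return list of segments (snapshot segments excluded). Each element has
#'   `session`, `condition`, `kind`, `onset_s`, `time_h` (segment onset in
#'   hours), `behavior` (data frame: `time_s` absolute seconds,
#'   `running_speed` cm/s, `visual_flow`, `stimulus_state`,
#'   `orientation_deg`), `events` (data frame: `time_s`, `kind`,
#'   `orientation_deg`), and for grating segments the `trials` table.
#' @export
simulate_behavior <- function(schedule, cfg = generator_config(), seed = 1L) {
  stopifnot(inherits(schedule, "ieg_schedule"))
  with_seed(seed, {
    segs <- list()
    for (s in schedule$sessions) {
      closed_flow <- NULL
      for (j in seq_len(nrow(s$segments))) {
        kind <- s$segments$kind[j]
        if (kind == "ieg_snapshot") next
        dur <- s$segments$duration_s[j]
        onset <- s$segments$onset_s[j]
        seg <- .simulate_segment(kind, dur, onset, cfg, closed_flow)
        if (kind == "closed_loop") closed_flow <- seg$behavior$visual_flow
        seg$session <- s$session
        seg$condition <- s$condition
        segs[[length(segs) + 1L]] <- seg
      }
    }
    segs
  })
}

.simulate_segment <- function(kind, dur, onset, cfg, closed_flow = NULL) {
  dt <- 1 / cfg$trace_rate_hz
  n <- as.integer(round(dur * cfg$trace_rate_hz))
  time_s <- onset + (seq_len(n) - 1) * dt
  run <- .simulate_running(n, dt, cfg)
  flow <- numeric(n)
  state <- rep("dark", n)
  ori <- rep(NA_real_, n)
  events <- data.frame(time_s = numeric(0), kind = character(0),
                       orientation_deg = numeric(0))
  trials <- NULL

  if (kind == "closed_loop") {
    flow <- cfg$closed_loop_gain * run$speed
    state <- rep("flow", n)
    halts <- .insert_halts(run$speed, dt, cfg)
    for (h in halts) {
      idx <- h:min(n, h + as.integer(round(cfg$halt_duration_s / dt)) - 1L)
      flow[idx] <- 0
      state[idx] <- "halt"
    }
    if (length(halts)) {
      events <- rbind(events, data.frame(time_s = time_s[halts],
                                         kind = "mismatch",
                                         orientation_deg = NA_real_))
    }
  } else if (kind == "open_loop") {
    if (is.null(closed_flow)) {
      stop("open-loop segment without a preceding closed-loop segment",
           call. = FALSE)
    }
    m <- min(n, length(closed_flow))
    flow[seq_len(m)] <- closed_flow[seq_len(m)]
    state <- rep("flow", n)
    state[flow == 0] <- "halt"
  } else if (kind == "grating") {
    trials <- build_grating_block(cfg$grating_n_orientations,
                                  cfg$grating_n_reps,
                                  cfg$grating_standing_s,
                                  cfg$grating_drifting_s,
                                  seed = sample.int(.Machine$integer.max, 1))
    for (k in seq_len(nrow(trials))) {
      i0 <- as.integer(round(trials$onset_s[k] / dt)) + 1L
      i1 <- i0 + as.integer(round(trials$standing_s[k] / dt)) - 1L
      i2 <- i1 + as.integer(round(trials$drifting_s[k] / dt))
      if (i0 > n) break
      state[i0:min(n, i1)] <- "standing"
      if (i1 + 1L <= n) state[(i1 + 1L):min(n, i2)] <- "drifting"
      ori[i0:min(n, i2)] <- trials$orientation_deg[k]
    }
    drift_on <- time_s[pmin(n, as.integer(round((trials$onset_s +
      trials$standing_s) / dt)) + 1L)]
    events <- rbind(events, data.frame(time_s = drift_on,
                                       kind = "grating_onset",
                                       orientation_deg = trials$orientation_deg))
  }

  if (length(run$onsets)) {
    events <- rbind(events, data.frame(time_s = time_s[run$onsets],
                                       kind = "run_onset_true",
                                       orientation_deg = NA_real_))
  }
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  list(kind = kind, onset_s = onset, duration_s = dur, time_h = onset / 3600,
       behavior = data.frame(time_s = time_s, running_speed = run$speed,
                             visual_flow = flow, stimulus_state = state,
                             orientation_deg = ori),
       events = events, trials = trials)
}

# Two-state rest/run process with exponential dwells; returns speed and the
# indices of true run-bout onsets.
.simulate_running <- function(n, dt, cfg) {
  if (n == 0L) return(list(speed = numeric(0), onsets = integer(0)))
  p_run <- cfg$run_dwell_s / (cfg$run_dwell_s + cfg$rest_dwell_s)
  speed <- numeric(n)
  onsets <- integer(0)
  state <- stats::runif(1) < p_run
  i <- 1L
  while (i <= n) {
    mean_dwell <- if (state) cfg$run_dwell_s else cfg$rest_dwell_s
    dwell <- if (is.finite(mean_dwell)) stats::rexp(1, 1 / mean_dwell) else Inf
    len <- if (is.finite(dwell)) max(1L, as.integer(round(min(dwell / dt, n))))
           else n
    idx <- i:min(n, i + len - 1L)
    if (state) {
      target <- max(2 * cfg$run_threshold,
                    stats::rnorm(1, cfg$run_speed_mean, cfg$run_speed_sd))
      jitter <- as.numeric(stats::filter(stats::rnorm(length(idx), 0, 1.5),
                                         0.8, method = "recursive"))
      speed[idx] <- pmax(0, target + jitter)
      if (i > 1L) onsets <- c(onsets, i)
    }
    i <- i + len
    state <- !state
  }
  list(speed = speed, onsets = onsets)
}

# Thinned Poisson halt onsets (sample indices), gated on running and spaced
# by the refractory gap.
.insert_halts <- function(speed, dt, cfg) {
  cand <- which(speed > cfg$run_threshold &
                  stats::runif(length(speed)) < cfg$halt_rate_hz * dt)
  keep <- integer(0)
  last <- -Inf
  gap <- cfg$halt_refractory_s / dt
  for (i in cand) {
    if (i - last >= gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}
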