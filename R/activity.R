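#' Simulate calcium fluorescence for a list of behavior segments
#'
#' Per neuron, the instantaneous firing rate is
#' `rate = mod * (baseline + visual_weight * v(t) + motor_weight * m(t) +
#' mismatch_weight * h(t))`, rectified at zero, where `v(t)` is the visual
#' drive (visual flow scaled by the typical running speed, or grating drive
#' weighted by orientation tuning), `m(t)` the normalized running speed, and
#' `h(t)` an indicator of a visual-flow halt while the animal is running
#' (visuomotor mismatch). `mod` is a per-neuron, per-segment lognormal
#' excitability modulation (slow rate fluctuations across the session).
#' Spikes are drawn as an inhomogeneous Poisson process on the trace grid,
#' convolved with a single-exponential calcium kernel (`calcium_tau_s`), and
#' white noise is added at `snr_activity` (transient amplitude over noise SD).
#'
#' @param segments output of [simulate_behavior()].
#' @param truth ground-truth table from [make_ground_truth()].
#' @param cfg an [generator_config()] object.
#' @param seed integer seed.
#' @return the segment list with a `fluor` matrix (neurons x samples, raw
#'   fluorescence, baseline 1) added to each segment.
#' @export
simulate_activity <- function(segments, truth, cfg = generator_config(),
                              seed = 1L) {
  n <- nrow(truth)
  if (n != cfg$n_neurons_per_mouse) {
    stop("ground truth and config disagree on neuron count", call. = FALSE)
  }
  amp <- 0.2  # fluorescence transient amplitude per spike (dF/F units)
  with_seed(seed, {
    for (k in seq_along(segments)) {
      seg <- segments[[k]]
      b <- seg$behavior
      nt <- nrow(b)
      if (nt == 0L) {
        segments[[k]]$fluor <- matrix(numeric(0), nrow = n, ncol = 0)
        next
      }
      dt <- 1 / cfg$trace_rate_hz
      v <- .visual_drive(b, truth, cfg)             # n x nt
      m_t <- b$running_speed / cfg$run_speed_mean   # length nt
      h_t <- as.numeric(b$stimulus_state == "halt" &
                          b$running_speed > cfg$run_threshold)
      rate <- v * truth$visual_weight +
        outer(truth$motor_weight, m_t) +
        outer(truth$mismatch_weight, h_t) +
        truth$baseline_rate_hz
      mod <- stats::rlnorm(n, -cfg$rate_mod_sdlog^2 / 2, cfg$rate_mod_sdlog)
      rate <- pmax(rate * mod, 0)
      spikes <- matrix(stats::rpois(n * nt, rate * dt), nrow = n)
      ca <- .calcium_convolve(spikes, exp(-dt / cfg$calcium_tau_s))
      noise_sd <- if (cfg$snr_activity > 0) amp / cfg$snr_activity else 0
      fl <- 1 + amp * ca
      if (noise_sd > 0) fl <- fl + matrix(stats::rnorm(n * nt, 0, noise_sd),
                                          nrow = n)
      segments[[k]]$fluor <- fl
    }
    segments
  })
}

# Visual drive matrix (neurons x samples): flow-driven during loop segments,
# orientation-tuned during gratings (standing gratings drive at 30%).
.visual_drive <- function(b, truth, cfg) {
  n <- nrow(truth)
  nt <- nrow(b)
  v <- matrix(0, n, nt)
  flow_idx <- b$stimulus_state %in% c("flow", "halt")
  if (any(flow_idx)) {
    v[, flow_idx] <- matrix(rep(b$visual_flow[flow_idx] /
                                  (cfg$closed_loop_gain * cfg$run_speed_mean),
                                each = n), nrow = n)
  }
  grat_idx <- which(b$stimulus_state %in% c("standing", "drifting"))
  if (length(grat_idx)) {
    tune <- outer(truth$preferred_orientation, b$orientation_deg[grat_idx],
                  FUN = orientation_tuning)
    gain <- ifelse(b$stimulus_state[grat_idx] == "drifting", 1, 0.3)
    v[, grat_idx] <- tune * rep(gain, each = n)
  }
  v
}

# Exponential calcium kernel as a first-order recursive filter over time.
.calcium_convolve <- function(spikes, decay) {
  nt <- ncol(spikes)
  if (nt == 0L) return(spikes)
  ca <- spikes
  for (t in seq_len(nt)[-1]) ca[, t] <- ca[, t - 1] * decay + spikes[, t]
  ca
}
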