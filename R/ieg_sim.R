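#' Simulate IEG reporter snapshots from simulated activity
#'
#' Expression induced at snapshot time `t` integrates the preceding activity
#' through the causal gamma-shaped [induction_kernel()]:
#' \deqn{raw_i(t) = base_i + g \cdot cg_{c(t)} \cdot d_{i,c(t)} \cdot S_i(t)
#'   + \epsilon}
#' \deqn{S_i(t) = \sum_{seg} w_{seg} \, u_i(seg) \, K(t - t_{seg}) +
#'   \bar{u}_i \left( \int_0^\infty K - \sum_{seg} w_{seg} K(t - t_{seg})
#'   \right)}
#' where `u_i(seg) = (1 - w) * mean(dff) + w * max(dff)` is the segment
#' activity summary with mixture weight `w = coupling_mode`, `t_seg` the
#' segment midpoint, `g` the coupling gain, `cg` the per-condition gain and
#' `d` the per-neuron, per-condition expression drive from the ground truth.
#' Each recording stands in for the epoch it samples: its kernel weight
#' `w_seg` is the half-distance to the neighboring recordings, capped at
#' `rep_span_h`. Unmeasured time (before the experiment and between
#' sessions) is assumed to run at the neuron's mean activity `ubar_i`, which
#' closes the kernel integral so that expression is in steady state at the
#' first snapshot rather than ramping up over the session. Noise is white
#' with SD equal to the mean snapshot level divided by `snr_ieg`.
#'
#' @param segments segment list from [simulate_activity()], each carrying a
#'   `dff` matrix (see [simulate_mouse()]).
#' @param truth ground-truth table from [make_ground_truth()].
#' @param schedule the `ieg_schedule` the segments were generated from.
#' @param cfg an [generator_config()] object.
#' @param seed integer seed (expression noise).
#' @param rep_span_h cap, in hours, on the epoch each recording represents in
#'   the induction integral (default 0.25 h, the measurement cadence).
#' @param steady_state include the steady-state closure for unmeasured time
#'   (mean fill plus matched variance); disable for controlled experiments
#'   where only the measured segments should drive expression.
#' @return an object of class `ieg_snapshots`: list with `values` (neurons x
#'   timepoints, raw), `timepoint_h`, `session`, `condition`,
#'   `normalized = FALSE`.
#' @export
simulate_ieg <- function(segments, truth, schedule, cfg = generator_config(),
                         seed = 1L, rep_span_h = 0.25, steady_state = TRUE) {
  tp <- schedule_timepoints(schedule)
  span_end <- max(vapply(segments, function(s) s$onset_s + s$duration_s,
                         numeric(1))) / 3600
  if (any(tp$time_h < 0 | tp$time_h > span_end + 1e-9)) {
    stop("IEG snapshot time outside the simulated activity span",
         call. = FALSE)
  }
  n <- nrow(truth)
  u <- vapply(segments, function(s) segment_activity_summary(s$dff,
                                                             cfg$coupling_mode),
              numeric(n))                              # n x n_seg
  mid_h <- vapply(segments, function(s) s$time_h + s$duration_s / 7200,
                  numeric(1))
  dur_h <- vapply(segments, function(s) s$duration_s / 3600, numeric(1))
  # kernel weight: the epoch this recording stands in for (half-distance to
  # neighboring recordings, at least its own duration, capped at rep_span_h)
  half_gap <- if (length(mid_h) > 1) {
    d <- diff(sort(mid_h))
    (c(d[1], d) + c(d, d[length(d)])) / 2
  } else rep(rep_span_h, 1)
  w_h <- pmin(pmax(dur_h, half_gap[rank(mid_h)]), pmax(rep_span_h, dur_h))
  lags <- outer(mid_h, tp$time_h, function(a, b) b - a)  # n_seg x n_tp
  kmat <- induction_kernel(lags, cfg$induction_delay_h, cfg$ieg_decay_h,
                           cfg$induction_width_h) * w_h
  s_mat <- u %*% kmat                                   # n x n_tp
  # steady-state closure: unmeasured epochs run at the neuron's expected
  # activity (a deterministic function of ground truth and stimulus, so the
  # fill shares no sampling noise with the measured segments)
  fill_sd <- rep(0, nrow(tp))
  if (steady_state) {
    itot <- .kernel_integral(cfg$induction_delay_h, cfg$ieg_decay_h,
                             cfg$induction_width_h)
    resid <- pmax(0, itot - colSums(kmat))
    ubar <- .expected_summary(segments, truth, cfg, w_h, u)
    s_mat <- s_mat + outer(ubar, resid)
    # ...and fluctuates like measured epochs do: unmeasured-epoch variance
    # tops up each snapshot so early snapshots are as variable as late ones
    i2 <- .kernel_integral2(cfg$induction_delay_h, cfg$ieg_decay_h,
                            cfg$induction_width_h)
    sd_t <- stats::median(apply(u, 1, stats::sd), na.rm = TRUE)
    fill_sd <- sd_t * sqrt(pmax(0, mean(w_h) * i2 - colSums(kmat^2)))
  }

  s_mat <- s_mat + with_seed(.subseed(seed, 1L),
    matrix(stats::rnorm(length(s_mat), 0, rep(fill_sd, each = n)), nrow = n))
  drive <- as.matrix(truth[, paste0("drive_c", tp$condition), drop = FALSE])
  sig <- cfg$coupling_gain * drive * s_mat *
    rep(cfg$condition_gain[tp$condition], each = n)
  base <- truth$ieg_baseline
  noise_sd <- if (cfg$snr_ieg > 0) (mean(base) + mean(sig)) / cfg$snr_ieg else 0
  vals <- base + sig
  if (noise_sd > 0) {
    vals <- vals + with_seed(.subseed(seed, 2L),
                             matrix(stats::rnorm(length(vals), 0, noise_sd),
                                    nrow = n))
  }
  structure(list(values = vals, timepoint_h = tp$time_h,
                 session = tp$session, condition = tp$condition,
                 normalized = FALSE),
            class = "ieg_snapshots")
}

# Expected per-neuron activity summary over the schedule: the weighted mean
# of each neuron's expected firing rate (mod = 1) across segments, rescaled
# to the empirical summary scale. Deterministic given ground truth and
# stimulus, so steady-state fill terms carry the stable across-neuron
# structure without sharing sampling noise with any measured segment.
.expected_summary <- function(segments, truth, cfg, w_h, u) {
  prate <- vapply(segments, function(s) {
    b <- s$behavior
    if (nrow(b) == 0L) return(truth$baseline_rate_hz)
    vbar <- rowMeans(.visual_drive(b, truth, cfg))
    truth$baseline_rate_hz + truth$visual_weight * vbar +
      truth$motor_weight * mean(b$running_speed / cfg$run_speed_mean) +
      truth$mismatch_weight * mean(b$stimulus_state == "halt" &
                                     b$running_speed > cfg$run_threshold)
  }, numeric(nrow(truth)))
  pbar <- as.vector(prate %*% w_h) / sum(w_h)
  scale <- mean(u, na.rm = TRUE) / mean(pbar)
  pbar * scale
}

# Closed-form integral of the unit-mode induction kernel:
# int_0^inf (s/p)^a exp(a (1 - s/p)) ds = p e^a Gamma(a+1) / a^(a+1)
.kernel_integral <- function(peak_h, decay_h, width_h = NA_real_) {
  if (!is.na(width_h)) decay_h <- width_h^2 / peak_h
  a <- peak_h / decay_h
  peak_h * exp(a + lgamma(a + 1) - (a + 1) * log(a))
}

# ... and of its square: int K^2 = p e^(2a) Gamma(2a+1) / (2a)^(2a+1)
.kernel_integral2 <- function(peak_h, decay_h, width_h = NA_real_) {
  if (!is.na(width_h)) decay_h <- width_h^2 / peak_h
  a <- peak_h / decay_h
  peak_h * exp(2 * a + lgamma(2 * a + 1) - (2 * a + 1) * log(2 * a))
}

#' Segment activity summary
#'
#' Convex mean/max mixture of a segment's per-neuron dF/F:
#' `(1 - w) * mean + w * max`, the drive the generator feeds into IEG
#' induction and the statistic the coupling analysis summarizes per
#' measurement timepoint.
#'
#' @param dff neurons x samples dF/F matrix.
#' @param w mixture weight on the maximum, in `[0, 1]`.
#' @return numeric vector, one value per neuron.
#' @export
segment_activity_summary <- function(dff, w = 0) {
  if (ncol(dff) == 0L) return(rep(NA_real_, nrow(dff)))
  mn <- rowMeans(dff)
  if (w == 0) return(mn)
  mx <- dff[cbind(seq_len(nrow(dff)), max.col(dff, ties.method = "first"))]
  (1 - w) * mn + w * mx
}
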