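#' Detect running onsets
#'
#' An onset is an upward crossing of `threshold` by the running-speed trace
#' after a quiescent period of at least `quiet_s` (speed below threshold
#' throughout) that is followed by at least `run_s` of sustained running.
#'
#' @param behavior a behavior data frame (`time_s`, `running_speed`).
#' @param rate_hz sampling rate of the trace grid.
#' @param threshold speed threshold (cm/s).
#' @param quiet_s minimum quiescence before the crossing (s).
#' @param run_s minimum sustained running after the crossing (s).
#' @return event table: data frame `time_s`, `kind = "running_onset"`.
#' @export
detect_running_onsets <- function(behavior, rate_hz = 10, threshold = 1,
                                  quiet_s = 1, run_s = 1) {
  sp <- behavior$running_speed
  n <- length(sp)
  above <- sp > threshold
  nq <- max(1L, as.integer(round(quiet_s * rate_hz)))
  nr <- max(1L, as.integer(round(run_s * rate_hz)))
  onsets <- integer(0)
  cand <- which(above & !c(TRUE, above[-n]))  # upward crossings
  for (i in cand) {
    if (i - nq < 1L || i + nr - 1L > n) next
    if (any(above[(i - nq):(i - 1L)])) next
    if (!all(above[i:(i + nr - 1L)])) next
    onsets <- c(onsets, i)
  }
  data.frame(time_s = behavior$time_s[onsets],
             kind = rep("running_onset", length(onsets)))
}

#' Event-triggered dF/F responses
#'
#' Per neuron and event, the mean dF/F over the response window
#' `[0, response_s)` after event onset minus the mean over the baseline
#' window (default -500 ms to -100 ms before onset); averaged over events.
#' Events whose windows are truncated by the segment edges are dropped.
#'
#' @param dff neurons x samples dF/F matrix of one segment.
#' @param time_s sample times of the segment (absolute seconds).
#' @param event_times_s event onset times (absolute seconds).
#' @param rate_hz sampling rate (Hz).
#' @param baseline_s baseline window relative to onset, `c(start, end)` in
#'   seconds (half-open).
#' @param response_s response window length in seconds (window `[0,
#'   response_s)`).
#' @return list with `mean_response` (per neuron, `NA` if no valid event),
#'   `per_event` (neurons x events matrix), `n_events` (events retained),
#'   `n_dropped`.
#' @export
event_triggered_response <- function(dff, time_s, event_times_s,
                                     rate_hz = 10,
                                     baseline_s = c(-0.5, -0.1),
                                     response_s = 1.5) {
  stopifnot(ncol(dff) == length(time_s))
  dt <- 1 / rate_hz
  n <- nrow(dff)
  nt <- ncol(dff)
  b0 <- as.integer(round(baseline_s[1] / dt))
  b1 <- as.integer(round(baseline_s[2] / dt)) - 1L
  r1 <- as.integer(round(response_s / dt)) - 1L
  per <- list()
  dropped <- 0L
  for (ev in event_times_s) {
    i0 <- which.min(abs(time_s - ev))
    if (abs(time_s[i0] - ev) > dt) { dropped <- dropped + 1L; next }
    if (i0 + b0 < 1L || i0 + r1 > nt) { dropped <- dropped + 1L; next }
    base <- rowMeans(dff[, (i0 + b0):(i0 + b1), drop = FALSE])
    resp <- rowMeans(dff[, i0:(i0 + r1), drop = FALSE])
    per[[length(per) + 1L]] <- resp - base
  }
  if (!length(per)) {
    return(list(mean_response = rep(NA_real_, n),
                per_event = matrix(numeric(0), nrow = n), n_events = 0L,
                n_dropped = dropped))
  }
  pe <- do.call(cbind, per)
  list(mean_response = rowMeans(pe), per_event = pe,
       n_events = ncol(pe), n_dropped = dropped)
}

#' Population z-score
#'
#' Subtracts the mean and divides by the standard deviation of the response
#' over all neurons, so the scored population has mean 0 and SD 1.
#'
#' @param responses per-neuron values (`NA` allowed, preserved).
#' @return z-scores of the same length.
#' @export
zscore_over_population <- function(responses) {
  x <- responses[!is.na(responses)]
  if (length(x) < 2) stop("need >= 2 neurons to z-score", call. = FALSE)
  s <- sqrt(mean((x - mean(x))^2))  # population SD over all neurons
  if (s == 0) stop("zero standard deviation across the population",
                   call. = FALSE)
  (responses - mean(x)) / s
}

#' Select high-IEG neurons
#'
#' Ranks neurons by their mean expression over the snapshots of the reference
#' sessions (default convention: the first day of a condition, i.e. both
#' same-day sessions) and returns the top `round-half-up(fraction * N)`
#' neurons. Ties break deterministically towards the lower neuron id.
#'
#' @param ieg an `ieg_snapshots` object, or a neurons x timepoints matrix.
#' @param reference_sessions session ids defining the reference day (used
#'   when `ieg` is an `ieg_snapshots`); `NULL` uses all timepoints.
#' @param fraction fraction of neurons to select, in `(0, 1]`.
#' @return integer vector of selected neuron indices (row indices), ordered
#'   by decreasing expression.
#' @export
select_high_ieg <- function(ieg, reference_sessions = NULL, fraction = 0.10) {
  if (!(is.numeric(fraction) && length(fraction) == 1 && fraction > 0 &&
          fraction <= 1)) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (inherits(ieg, "ieg_snapshots")) {
    cols <- if (is.null(reference_sessions)) seq_along(ieg$session) else
      which(ieg$session %in% reference_sessions)
    if (!length(cols)) stop("reference sessions not present", call. = FALSE)
    vals <- ieg$values[, cols, drop = FALSE]
  } else {
    vals <- ieg
  }
  score <- rowMeans(vals, na.rm = TRUE)
  n_sel <- floor(fraction * length(score) + 0.5)  # round half up
  ord <- order(-score, seq_along(score))          # ties -> lower neuron id
  ord[seq_len(n_sel)]
}

#' Per-neuron behavior correlations in open loop
#'
#' Pearson correlation of each neuron's dF/F, concatenated over the open-loop
#' segments, with the concatenated running trace and, separately, with the
#' concatenated visual-flow trace.
#'
#' @param mouse a `mouse_dataset`.
#' @param conditions conditions whose open-loop segments are used
#'   (default 2 and 3).
#' @return data frame: `neuron`, `r_running`, `r_flow` (`NA` when the
#'   behavior trace is constant).
#' @export
behavior_correlations <- function(mouse, conditions = c(2, 3)) {
  segs <- Filter(function(s) s$kind == "open_loop" &&
                   s$condition %in% conditions, mouse$segments)
  if (!length(segs)) stop("no open-loop segments", call. = FALSE)
  dff <- do.call(cbind, lapply(segs, `[[`, "dff"))
  run <- unlist(lapply(segs, function(s) s$behavior$running_speed))
  flow <- unlist(lapply(segs, function(s) s$behavior$visual_flow))
  corr_or_na <- function(b) {
    if (stats::sd(b) == 0) return(rep(NA_real_, nrow(dff)))
    as.numeric(suppressWarnings(stats::cor(t(dff), b,
                                           use = "pairwise.complete.obs")))
  }
  data.frame(neuron = seq_len(nrow(dff)),
             r_running = corr_or_na(run), r_flow = corr_or_na(flow))
}

#' Group contrast of a per-neuron statistic
#'
#' One-sample t-test of the group mean against 0 and two-sample pooled t-test
#' of group vs the rest, with means and SEMs.
#'
#' @param values per-neuron statistic (e.g. z-scored responses).
#' @param group indices of the high-IEG group.
#' @return list with `group_mean`, `group_sem`, `rest_mean`, `rest_sem`,
#'   `vs_zero` and `vs_rest` (both `TestResult` or `NULL` when a group is too
#'   small or degenerate).
#' @export
group_contrast <- function(values, group) {
  stopifnot(length(group) >= 1, length(group) < length(values))
  g <- values[group]
  r <- values[-group]
  g <- g[!is.na(g)]; r <- r[!is.na(r)]
  vs_zero <- if (length(g) >= 2 && stats::sd(g) > 0) t_test_one_sample(g) else NULL
  vs_rest <- if (length(g) >= 2 && length(r) >= 2 &&
                   stats::sd(c(g, r)) > 0) t_test_two_sample(g, r) else NULL
  list(group_mean = mean(g), group_sem = .sem(g),
       rest_mean = mean(r), rest_sem = .sem(r),
       vs_zero = vs_zero, vs_rest = vs_rest)
}

#' Pooled event-triggered z-scores for a mouse
#'
#' Convenience wrapper for the functional characterization: collects events
#' of one kind across the sessions of the given conditions, computes
#' event-triggered responses per segment, averages per neuron over all
#' events, and z-scores over the population.
#'
#' @param mouse a `mouse_dataset`.
#' @param event_kind `"running_onset"` (detected in dark segments),
#'   `"grating_onset"` (drifting onsets from the stimulus log) or
#'   `"mismatch"` (closed-loop flow halts while running).
#' @param conditions conditions pooled over.
#' @param ... passed to [event_triggered_response()] /
#'   [detect_running_onsets()].
#' @return list with `response` (per-neuron mean baseline-subtracted
#'   response), `zscore`, `n_events`.
#' @export
pooled_event_zscores <- function(mouse, event_kind, conditions = c(2, 3),
                                 ...) {
  rate <- mouse$cfg$trace_rate_hz
  acc <- NULL
  n_ev <- 0L
  for (s in mouse$segments) {
    if (!s$condition %in% conditions) next
    ev <- switch(event_kind,
      running_onset = if (s$kind == "dark") {
        detect_running_onsets(s$behavior, rate_hz = rate,
                              threshold = mouse$cfg$run_threshold)$time_s
      } else numeric(0),
      grating_onset = s$events$time_s[s$events$kind == "grating_onset"],
      mismatch = s$events$time_s[s$events$kind == "mismatch"],
      stop("unknown event kind", call. = FALSE))
    if (!length(ev)) next
    etr <- event_triggered_response(s$dff, s$behavior$time_s, ev,
                                    rate_hz = rate, ...)
    if (etr$n_events == 0L) next
    acc <- if (is.null(acc)) etr$per_event else cbind(acc, etr$per_event)
    n_ev <- n_ev + etr$n_events
  }
  if (is.null(acc)) {
    return(list(response = rep(NA_real_, nrow(mouse$truth)),
                zscore = rep(NA_real_, nrow(mouse$truth)), n_events = 0L))
  }
  resp <- rowMeans(acc)
  list(response = resp, zscore = zscore_over_population(resp),
       n_events = n_ev)
}
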