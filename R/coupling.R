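#' Per-timepoint activity summaries
#'
#' Collapses each session's dF/F into one population vector per measurement
#' timepoint: per neuron, the mean (or the mean/max mixture's pure max) of
#' the dF/F samples pooled over the session's selected activity segments.
#'
#' @param mouse a `mouse_dataset` from [simulate_mouse()], or a plain list
#'   with `segments` (each with `dff`, `session`) and `ieg_raw`.
#' @param mode `"mean"` or `"max"` of the pooled samples.
#' @param segments `"all"` pools every activity segment of the session,
#'   `"first"` uses only the first one (the convention for session-wise
#'   activity/expression correlations), or a character vector of segment
#'   kinds (e.g. `"grating"` for stimulation-block activity).
#' @return an `activity_summary`: list with `values` (neurons x timepoints),
#'   `timepoint_h` (the session's first snapshot time), `session`,
#'   `condition`, `mode`.
#' @export
summarize_activity <- function(mouse, mode = c("mean", "max"),
                               segments = "all") {
  mode <- match.arg(mode)
  seg_session <- vapply(mouse$segments, `[[`, integer(1), "session")
  tp <- data.frame(session = mouse$ieg_raw$session,
                   condition = mouse$ieg_raw$condition,
                   time_h = mouse$ieg_raw$timepoint_h)
  tp <- tp[!duplicated(tp$session), , drop = FALSE]  # one timepoint per session
  n <- nrow(mouse$truth)
  vals <- matrix(NA_real_, n, nrow(tp))
  for (j in seq_len(nrow(tp))) {
    idx <- which(seg_session == tp$session[j])
    if (identical(segments, "first")) {
      idx <- idx[1]
    } else if (!identical(segments, "all")) {
      kinds <- vapply(mouse$segments[idx], `[[`, character(1), "kind")
      idx <- idx[kinds %in% segments]
    }
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    pooled <- do.call(cbind, lapply(mouse$segments[idx], `[[`, "dff"))
    if (is.null(pooled) || ncol(pooled) == 0) next
    vals[, j] <- if (mode == "mean") rowMeans(pooled) else
      apply(pooled, 1, max)
  }
  structure(list(values = vals, timepoint_h = tp$time_h,
                 session = tp$session, condition = tp$condition, mode = mode),
            class = "activity_summary")
}

#' Time-lagged population-vector correlation
#'
#' For each lag `L` on the grid, takes every pair of measurement timepoints
#' (activity timepoint `t_a`, expression timepoint `t_i`) with
#' `t_i - t_a = L` (within half a grid step), computes the Pearson
#' correlation across neurons between the activity population vector and the
#' expression population vector, and averages the pairwise correlations at
#' that lag. Positive lags mean the activity measurement preceded the
#' expression measurement. Lags with no contributing pair are `NA`.
#'
#' @param act an `activity_summary` (see [summarize_activity()]).
#' @param ieg an `ieg_snapshots` object (normalized) or a neurons x
#'   timepoints matrix with times in `timepoint_h`.
#' @param lag_grid_h lag grid in hours (default -2 h to +6 h in 15-min steps,
#'   the measurement cadence).
#' @param timepoint_h expression snapshot times when `ieg` is a bare matrix.
#' @return a `correlation_curve` data frame: `lag_h`, `r`, `n_pairs`.
#' @export
lagged_population_correlation <- function(act, ieg,
                                          lag_grid_h = seq(-2, 6, by = 0.25),
                                          timepoint_h = NULL) {
  if (inherits(ieg, "ieg_snapshots")) {
    timepoint_h <- ieg$timepoint_h
    ieg <- ieg$values
  }
  av <- if (inherits(act, "activity_summary")) act$values else act
  at <- if (inherits(act, "activity_summary")) act$timepoint_h else
    attr(act, "timepoint_h")
  stopifnot(nrow(av) == nrow(ieg), length(timepoint_h) == ncol(ieg),
            length(at) == ncol(av))
  step <- if (length(lag_grid_h) > 1) min(diff(sort(lag_grid_h))) else 0.25
  r_sum <- n_pair <- numeric(length(lag_grid_h))
  for (a in seq_along(at)) {
    if (all(is.na(av[, a]))) next
    for (i in seq_along(timepoint_h)) {
      lag <- timepoint_h[i] - at[a]
      k <- which(abs(lag_grid_h - lag) <= step / 2 + 1e-9)
      if (!length(k)) next
      k <- k[1]
      r <- suppressWarnings(stats::cor(av[, a], ieg[, i],
                                       use = "complete.obs"))
      if (is.na(r)) next
      r_sum[k] <- r_sum[k] + r
      n_pair[k] <- n_pair[k] + 1
    }
  }
  out <- data.frame(lag_h = lag_grid_h,
                    r = ifelse(n_pair > 0, r_sum / pmax(n_pair, 1), NA_real_),
                    n_pairs = as.integer(n_pair))
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Peak statistics of per-mouse correlation curves
#'
#' Per mouse, the lag of the maximum correlation (earliest lag on ties) and
#' the value at the maximum; across mice, mean and SEM of both. Because the
#' curve is flat near its top relative to the 15-min grid, a refined sub-grid
#' peak lag is also reported: a quadratic is fit to the curve within
#' `refine_window_h` of the argmax and its vertex taken (falling back to the
#' raw argmax if the fit is not concave).
#'
#' @param curves a list of `correlation_curve` data frames (one per mouse).
#' @param refine_window_h half-width (hours) of the quadratic-fit window.
#' @return list with `per_mouse` (data frame: `mouse`, `peak_lag_h`,
#'   `peak_lag_refined_h`, `peak_r`), `mean_lag_h`, `sem_lag_h`,
#'   `mean_lag_refined_h`, `sem_lag_refined_h`, `mean_r`, `sem_r`.
#' @export
peak_statistics <- function(curves, refine_window_h = 1) {
  if (inherits(curves, "data.frame")) curves <- list(curves)
  per <- lapply(seq_along(curves), function(m) {
    cc <- curves[[m]]
    ok <- !is.na(cc$r)
    if (!any(ok)) stop("correlation curve with no valid lag", call. = FALSE)
    mx <- max(cc$r[ok])
    lag <- min(cc$lag_h[ok][cc$r[ok] >= mx - 1e-12])  # earliest-lag tie-break
    data.frame(mouse = m, peak_lag_h = lag,
               peak_lag_refined_h = .refine_peak(cc$lag_h[ok], cc$r[ok], lag,
                                                 refine_window_h),
               peak_r = mx)
  })
  per <- do.call(rbind, per)
  list(per_mouse = per,
       mean_lag_h = mean(per$peak_lag_h), sem_lag_h = .sem(per$peak_lag_h),
       mean_lag_refined_h = mean(per$peak_lag_refined_h),
       sem_lag_refined_h = .sem(per$peak_lag_refined_h),
       mean_r = mean(per$peak_r), sem_r = .sem(per$peak_r))
}

# Quadratic vertex within a window around the raw argmax, clamped to the
# window; the raw argmax when the local fit is not concave.
.refine_peak <- function(lag, r, lag0, window_h) {
  sel <- abs(lag - lag0) <= window_h + 1e-9
  if (sum(sel) < 4) return(lag0)
  x <- lag[sel] - lag0
  fit <- stats::lm(r[sel] ~ x + I(x^2))
  b <- stats::coef(fit)
  if (!is.finite(b[3]) || b[3] >= 0) return(lag0)
  vx <- -b[2] / (2 * b[3])
  lag0 + max(-window_h, min(window_h, vx))
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Coupling pipeline for a cohort
#'
#' Runs [summarize_activity()] and [lagged_population_correlation()] per
#' mouse (normalized expression), averages the curves over mice, and returns
#' per-mouse peaks plus the argmax of the mouse-averaged curve.
#'
#' @param cohort an `ieg_cohort` from [simulate_cohort()].
#' @param lag_grid_h lag grid in hours.
#' @param mode activity summary mode.
#' @param segments segment selection, see [summarize_activity()]; the default
#'   uses the dark recordings (the measurement segments proper -- stimulation
#'   blocks drive expression but are not measurement timepoints).
#' @return list with `curves` (per mouse), `mean_curve`, `peaks`
#'   ([peak_statistics()] output), `peak_lag_mean_curve_h`.
#' @export
coupling_pipeline <- function(cohort, lag_grid_h = seq(-2, 6, by = 0.25),
                              mode = "mean", segments = "dark") {
  curves <- lapply(cohort, function(m) {
    lagged_population_correlation(summarize_activity(m, mode, segments),
                                  m$ieg_norm, lag_grid_h)
  })
  rmat <- vapply(curves, `[[`, numeric(length(lag_grid_h)), "r")
  mean_r <- rowMeans(rmat, na.rm = TRUE)
  mean_curve <- data.frame(lag_h = lag_grid_h, r = mean_r)
  ok <- !is.na(mean_r)
  peak_lag <- min(lag_grid_h[ok][mean_r[ok] >= max(mean_r[ok]) - 1e-12])
  list(curves = curves, mean_curve = mean_curve,
       peaks = peak_statistics(curves), peak_lag_mean_curve_h = peak_lag)
}

#' Bootstrapped t-test group comparison
#'
#' Each group's per-mouse values are resampled with replacement `n_boot`
#' times (resampling unit = mouse); the resampled draws are pooled and a
#' two-sample pooled-variance t-test is performed on the pooled samples.
#'
#' @param group_a,group_b per-mouse statistics (e.g. peak correlations).
#' @param n_boot number of bootstrap resamples (default 5).
#' @param seed integer seed.
#' @return a `TestResult` (see [t_test_two_sample()]) with the resample draws
#'   in attribute `"draws"`.
#' @export
bootstrap_t_compare <- function(group_a, group_b, n_boot = 5, seed = 1L) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  draws <- with_seed(seed, list(
    a = unlist(lapply(seq_len(n_boot), function(i)
      sample(group_a, length(group_a), replace = TRUE))),
    b = unlist(lapply(seq_len(n_boot), function(i)
      sample(group_b, length(group_b), replace = TRUE)))
  ))
  if (stats::var(c(draws$a, draws$b)) == 0) {
    warning("degenerate bootstrap samples (zero variance); p reported as 1")
    res <- test_result(statistic = 0, p_value = 1, df = NA_real_,
                       n = c(length(draws$a), length(draws$b)),
                       method = "bootstrap_t", seed = seed)
  } else {
    res <- t_test_two_sample(draws$a, draws$b)
    res$method <- "bootstrap_t"
    res$seed <- seed
  }
  attr(res, "draws") <- draws
  res
}

#' Mean- vs max-activity coupling contrast
#'
#' For every mouse and session, correlates (across neurons) the mean and,
#' separately, the maximum dF/F of the session's first recording segment with
#' the last normalized expression snapshot of that session; session-averaged
#' correlations per mouse, compared between modes with a paired t-test.
#'
#' @param cohort an `ieg_cohort`.
#' @return list with `per_mouse` (data frame: `mouse`, `r_mean`, `r_max`) and
#'   `test` (paired t-test, `NULL` when fewer than 2 mice).
#' @export
mean_vs_max_contrast <- function(cohort) {
  per <- lapply(seq_along(cohort), function(mi) {
    m <- cohort[[mi]]
    r2 <- vapply(c("mean", "max"), function(mode) {
      act <- summarize_activity(m, mode, segments = "first")
      rs <- vapply(seq_along(act$session), function(j) {
        snaps <- which(m$ieg_norm$session == act$session[j])
        if (!length(snaps)) return(NA_real_)
        last <- snaps[length(snaps)]
        suppressWarnings(stats::cor(act$values[, j],
                                    m$ieg_norm$values[, last],
                                    use = "complete.obs"))
      }, numeric(1))
      mean(rs, na.rm = TRUE)
    }, numeric(1))
    data.frame(mouse = mi, r_mean = r2[["mean"]], r_max = r2[["max"]])
  })
  per <- do.call(rbind, per)
  ok <- is.finite(per$r_max) & is.finite(per$r_mean)
  test <- if (sum(ok) >= 2 ) t_test_paired(per$r_max[ok], per$r_mean[ok]) else NULL
  list(per_mouse = per, test = test)
}
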