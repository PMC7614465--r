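#' Per-mouse timecourse of mean activity or mean expression
#'
#' One value per mouse per measurement timepoint (one timepoint per session):
#' for `quantity = "activity"`, the mean over neurons of the per-neuron mean
#' dF/F pooled over all activity segments of the session; for
#' `quantity = "ieg"`, the mean over neurons of the normalized expression of
#' the session's last snapshot.
#'
#' @param cohort an `ieg_cohort`.
#' @param quantity `"activity"` or `"ieg"`.
#' @return a tidy data frame (`mouse`, `session`, `timepoint_h`, `condition`,
#'   `value`), class `timecourse_table`.
#' @export
build_timecourse <- function(cohort, quantity = c("activity", "ieg")) {
  quantity <- match.arg(quantity)
  rows <- lapply(seq_along(cohort), function(mi) {
    m <- cohort[[mi]]
    if (quantity == "activity") {
      act <- summarize_activity(m, "mean", segments = "all")
      data.frame(mouse = mi, session = act$session,
                 timepoint_h = act$timepoint_h, condition = act$condition,
                 value = colMeans(act$values, na.rm = TRUE))
    } else {
      sess <- unique(m$ieg_norm$session)
      idx <- vapply(sess, function(s) max(which(m$ieg_norm$session == s)),
                    integer(1))  # last snapshot per session
      data.frame(mouse = mi, session = sess,
                 timepoint_h = m$ieg_norm$timepoint_h[idx],
                 condition = m$ieg_norm$condition[idx],
                 value = colMeans(m$ieg_norm$values[, idx, drop = FALSE],
                                  na.rm = TRUE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("timecourse_table", "data.frame")
  out
}

#' Condition-boundary change statistic
#'
#' Per mouse, the change across a condition boundary is the mean of the first
#' two sessions of the following condition minus the mean of the last two
#' sessions of the previous condition; across mice, mean +/- SEM and a paired
#' t-test between the two window means.
#'
#' @param tc a `timecourse_table` (see [build_timecourse()]).
#' @param boundary integer pair `c(previous, next)` condition ids, e.g.
#'   `c(2, 3)`.
#' @param n_sessions sessions averaged on each side of the boundary
#'   (default 2).
#' @return list with `per_mouse` (data frame: `mouse`, `before`, `after`,
#'   `change`), `mean_change`, `sem_change`, `test` (paired t-test; `NULL`
#'   with fewer than 2 mice).
#' @export
condition_change <- function(tc, boundary = c(2, 3), n_sessions = 2) {
  stopifnot(length(boundary) == 2)
  per <- lapply(unique(tc$mouse), function(mi) {
    d <- tc[tc$mouse == mi, ]
    d <- d[order(d$session), ]
    prev <- d$value[d$condition == boundary[1]]
    nxt <- d$value[d$condition == boundary[2]]
    if (length(prev) < n_sessions || length(nxt) < n_sessions) {
      stop(sprintf("mouse %s: need >= %d sessions on each side of boundary",
                   mi, n_sessions), call. = FALSE)
    }
    before <- mean(utils::tail(prev, n_sessions))
    after <- mean(utils::head(nxt, n_sessions))
    data.frame(mouse = mi, before = before, after = after,
               change = after - before)
  })
  per <- do.call(rbind, per)
  test <- if (nrow(per) >= 2) t_test_paired(per$after, per$before) else NULL
  list(per_mouse = per, mean_change = mean(per$change),
       sem_change = .sem(per$change), test = test)
}

#' Linear trend over selected conditions
#'
#' Ordinary least squares of the timecourse value on the timepoint, treating
#' each mouse-timepoint observation as independent; reports the slope,
#' R-squared and the p-value of the overall F statistic. Separately, a
#' first-degree fit per mouse is averaged for plotting.
#'
#' @param tc a `timecourse_table`.
#' @param condition_ids conditions included in the fit (default 2 and 3).
#' @return list with `slope`, `intercept`, `r_squared`, `test`
#'   (see [regression_f_test()]), and `mean_fit` (`intercept`, `slope`
#'   averaged over per-mouse fits).
#' @export
linear_trend <- function(tc, condition_ids = c(2, 3)) {
  d <- tc[tc$condition %in% condition_ids & !is.na(tc$value), ]
  if (nrow(d) < 3) stop("need >= 3 observations in the selected conditions",
                        call. = FALSE)
  res <- regression_f_test(d$timepoint_h, d$value)
  fits <- lapply(unique(d$mouse), function(mi) {
    dm <- d[d$mouse == mi, ]
    if (nrow(dm) < 2 || stats::sd(dm$timepoint_h) == 0) return(NULL)
    stats::coef(stats::lm(value ~ timepoint_h, data = dm))
  })
  fits <- do.call(rbind, Filter(Negate(is.null), fits))
  res$mean_fit <- if (!is.null(fits)) {
    c(intercept = mean(fits[, 1]), slope = mean(fits[, 2]))
  } else c(intercept = NA_real_, slope = NA_real_)
  res
}

#' Rank-order expression-pattern similarity
#'
#' Per mouse, the Spearman rank correlation between the expression population
#' vectors (across neurons) of every pair of measurement timepoints; the
#' per-mouse matrices are then averaged over mice. Rank correlation makes the
#' result invariant to any strictly monotone transform of expression, so raw
#' and min/median-normalized values give identical matrices. Timepoints with
#' a constant expression vector are marked missing (matrix row/column `NA`).
#'
#' @param cohort an `ieg_cohort`, or a list of neurons x timepoints matrices
#'   (one per mouse). One expression vector per session (last snapshot).
#' @param method rank correlation flavor, `"spearman"` (default) or
#'   `"kendall"`.
#' @return timepoints x timepoints similarity matrix averaged over mice.
#' @export
pattern_similarity <- function(cohort, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  mats <- lapply(cohort, function(m) {
    if (is.matrix(m)) return(m)
    sess <- unique(m$ieg_norm$session)
    idx <- vapply(sess, function(s) max(which(m$ieg_norm$session == s)),
                  integer(1))
    m$ieg_norm$values[, idx, drop = FALSE]
  })
  sims <- lapply(mats, function(v) {
    if (ncol(v) < 2 || nrow(v) < 3) {
      stop("pattern similarity needs >= 2 timepoints and >= 3 neurons",
           call. = FALSE)
    }
    s <- suppressWarnings(stats::cor(v, method = method,
                                     use = "pairwise.complete.obs"))
    const <- apply(v, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
    s[const, ] <- NA_real_
    s[, const] <- NA_real_
    diag(s)[!const] <- 1
    s
  })
  num <- Reduce(`+`, lapply(sims, function(s) ifelse(is.na(s), 0, s)))
  den <- Reduce(`+`, lapply(sims, function(s) (!is.na(s)) + 0))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
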