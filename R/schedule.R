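#' Build an experimental session schedule
#'
#' Two protocols are supported:
#' \describe{
#'   \item{`dark_adapt_fig1`}{dark-adapted mice measured every 15 min for 6 h:
#'     one baseline measurement, a single grating-stimulation block between
#'     the first and second measurement, then measurements every 15 min until
#'     6 h after stimulation - 25 measurement timepoints in total. Each
#'     measurement is an IEG snapshot plus a short activity recording in
#'     darkness.}
#'   \item{`learning_fig2`}{visuomotor-learning protocol: sessions every 12 h
#'     over 6 days (12 sessions, 4 per condition). Condition-1 sessions are
#'     dark-only recordings; condition-2/3 sessions contain 7 recordings
#'     (dark, closed-loop, open-loop, open-loop, dark, grating, dark). IEG
#'     snapshots are taken at the start and end of every session.}
#' }
#'
#' @param protocol `"dark_adapt_fig1"` or `"learning_fig2"`.
#' @param cfg an [generator_config()] object (segment durations, grating
#'   block structure).
#' @param n_sessions optional session count override for `learning_fig2`
#'   (default 12; 0 yields an empty schedule).
#' @return an object of class `ieg_schedule`: a list with `protocol` and
#'   `sessions`, each session a list with `session`, `time_h`, `condition`
#'   and a `segments` data frame (`kind`, `duration_s`, `onset_s` absolute
#'   seconds from experiment start). Snapshot segments have zero duration.
#' @export
build_schedule <- function(protocol, cfg = generator_config(),
                           n_sessions = NULL) {
  if (!is.character(protocol) || length(protocol) != 1 ||
      !protocol %in% c("dark_adapt_fig1", "learning_fig2")) {
    stop("unknown protocol: must be 'dark_adapt_fig1' or 'learning_fig2'",
         call. = FALSE)
  }
  grating_s <- with(cfg, grating_n_orientations * grating_n_reps *
                      (grating_standing_s + grating_drifting_s))
  sessions <- list()
  if (protocol == "dark_adapt_fig1") {
    times_h <- seq(0, 6, by = 0.25)  # baseline + every 15 min to +6 h
    for (i in seq_along(times_h)) {
      kinds <- c("ieg_snapshot", "dark")
      durs <- c(0, cfg$fig1_segment_s)
      if (i == 1L) {  # stimulation block between 1st and 2nd measurement
        kinds <- c(kinds, "grating")
        durs <- c(durs, grating_s)
      }
      sessions[[i]] <- .session(i, times_h[i], condition = 1L, kinds, durs)
    }
  } else {
    if (is.null(n_sessions)) n_sessions <- 12L
    n_sessions <- as.integer(n_sessions)
    if (n_sessions < 0) stop("n_sessions must be non-negative")
    for (i in seq_len(n_sessions)) {
      cond <- min(3L, (i - 1L) %/% 4L + 1L)
      if (cond == 1L) {
        kinds <- c("ieg_snapshot", "dark", "ieg_snapshot")
        durs <- c(0, cfg$fig2_segment_s, 0)
      } else {
        kinds <- c("ieg_snapshot", "dark", "closed_loop", "open_loop",
                   "open_loop", "dark", "grating", "dark", "ieg_snapshot")
        durs <- c(0, rep(cfg$fig2_segment_s, 5), grating_s,
                  cfg$fig2_segment_s, 0)
      }
      sessions[[i]] <- .session(i, (i - 1) * 12, condition = cond, kinds, durs)
    }
  }
  structure(list(protocol = protocol, sessions = sessions),
            class = "ieg_schedule")
}

.session <- function(id, time_h, condition, kinds, durs) {
  onset <- time_h * 3600 + cumsum(c(0, durs[-length(durs)]))
  list(session = as.integer(id), time_h = time_h,
       condition = as.integer(condition),
       segments = data.frame(kind = kinds, duration_s = durs,
                             onset_s = onset, stringsAsFactors = FALSE))
}

#' Measurement timepoints of a schedule
#'
#' One row per IEG snapshot: the measurement grid against which activity
#' summaries and expression snapshots are aligned.
#'
#' @param schedule an `ieg_schedule`.
#' @return data frame with `session`, `condition`, `time_h` (snapshot time in
#'   hours from experiment start).
#' @export
schedule_timepoints <- function(schedule) {
  stopifnot(inherits(schedule, "ieg_schedule"))
  out <- lapply(schedule$sessions, function(s) {
    snap <- s$segments[s$segments$kind == "ieg_snapshot", , drop = FALSE]
    if (nrow(snap) == 0) return(NULL)
    data.frame(session = s$session, condition = s$condition,
               time_h = snap$onset_s / 3600)
  })
  do.call(rbind, out)
}

#' Randomized grating-stimulation block
#'
#' Builds the grating trial list: each trial is a standing grating followed by
#' a drifting grating; every orientation appears exactly `n_reps` times, in a
#' seeded random order.
#'
#' @param n_orientations number of distinct directions (evenly spaced over
#'   360 degrees).
#' @param n_reps presentations per orientation.
#' @param standing_s,drifting_s standing / drifting durations per trial (s).
#' @param seed integer seed for the permutation.
#' @return data frame with `trial`, `orientation_deg`, `onset_s` (relative to
#'   block start), `standing_s`, `drifting_s`; `nrow = n_orientations * n_reps`.
#' @export
#' @examples
#' blk <- build_grating_block(8, 10, seed = 1)
#' nrow(blk)  # 80 trials
build_grating_block <- function(n_orientations, n_reps, standing_s = 2,
                                drifting_s = 3, seed = 1L) {
  if (n_orientations < 1 || n_reps < 1) {
    stop("n_orientations and n_reps must be positive", call. = FALSE)
  }
  n_orientations <- as.integer(n_orientations)
  n_reps <- as.integer(n_reps)
  oris <- seq(0, 360, length.out = n_orientations + 1)[seq_len(n_orientations)]
  seq_oris <- rep(oris, n_reps)
  ord <- with_seed(seed, sample.int(length(seq_oris)))
  trial_s <- standing_s + drifting_s
  n <- length(seq_oris)
  data.frame(trial = seq_len(n),
             orientation_deg = seq_oris[ord],
             onset_s = (seq_len(n) - 1) * trial_s,
             standing_s = standing_s,
             drifting_s = drifting_s)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
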