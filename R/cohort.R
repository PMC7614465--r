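#' Simulate one mouse end-to-end
#'
#' Draws ground truth, simulates behavior and calcium fluorescence for every
#' segment of the schedule, computes per-segment dF/F, and generates raw and
#' normalized IEG snapshots. All randomness derives from `seed`; the same
#' seed reproduces the dataset bit for bit.
#'
#' @param cfg an [generator_config()] object.
#' @param schedule an `ieg_schedule`; defaults to the protocol in
#'   `protocol`.
#' @param seed integer seed for this mouse.
#' @param mouse_id identifier stored in the dataset.
#' @param protocol protocol used when `schedule` is `NULL`.
#' @param keep_fluor keep raw fluorescence matrices (memory-heavy); dF/F is
#'   always kept.
#' @return a `mouse_dataset`: list with `mouse`, `ieg_line`, `truth`,
#'   `segments` (behavior, events, `dff`, optionally `fluor`), `ieg_raw`,
#'   `ieg_norm` (both `ieg_snapshots`), `schedule`, `cfg`.
#' @export
simulate_mouse <- function(cfg = generator_config(), schedule = NULL,
                           seed = 1L, mouse_id = 1L,
                           protocol = "dark_adapt_fig1", keep_fluor = TRUE) {
  if (is.null(schedule)) schedule <- build_schedule(protocol, cfg)
  truth <- with_seed(.subseed(seed, 1L), make_ground_truth(cfg))
  segs <- simulate_behavior(schedule, cfg, seed = .subseed(seed, 2L))
  segs <- simulate_activity(segs, truth, cfg, seed = .subseed(seed, 3L))
  for (k in seq_along(segs)) {
    segs[[k]]$dff <- compute_dff(segs[[k]]$fluor, rate_hz = cfg$trace_rate_hz)
    if (!keep_fluor) segs[[k]]$fluor <- NULL
  }
  ieg_raw <- simulate_ieg(segs, truth, schedule, cfg,
                          seed = .subseed(seed, 4L))
  structure(list(mouse = mouse_id, ieg_line = cfg$ieg_line, truth = truth,
                 segments = segs, ieg_raw = ieg_raw,
                 ieg_norm = normalize_ieg(ieg_raw),
                 schedule = schedule, cfg = cfg),
            class = "mouse_dataset")
}

#' Simulate a cohort of mice
#'
#' @param cfg an [generator_config()] object (`n_mice` mice).
#' @param protocol `"dark_adapt_fig1"` or `"learning_fig2"`.
#' @param seed cohort seed; mouse `i` uses a sub-seed derived from it.
#' @param schedule optional shared `ieg_schedule` overriding `protocol`.
#' @param keep_fluor see [simulate_mouse()].
#' @return list of `mouse_dataset` objects, class `ieg_cohort`.
#' @export
simulate_cohort <- function(cfg = generator_config(),
                            protocol = "dark_adapt_fig1",
                            seed = cfg$seed, schedule = NULL,
                            keep_fluor = TRUE) {
  if (is.null(schedule)) schedule <- build_schedule(protocol, cfg)
  mice <- lapply(seq_len(cfg$n_mice), function(i) {
    simulate_mouse(cfg, schedule, seed = .subseed(seed, 100L + i),
                   mouse_id = i, keep_fluor = keep_fluor)
  })
  structure(mice, class = "ieg_cohort")
}

# Deterministic 31-bit sub-seed stream (Lehmer step + offset).
.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

#' @export
print.mouse_dataset <- function(x, ...) {
  cat(sprintf("<mouse_dataset> mouse %s, line %s: %d neurons, %d segments, %d IEG snapshots\n",
              x$mouse, x$ieg_line, nrow(x$truth), length(x$segments),
              length(x$ieg_raw$timepoint_h)))
  invisible(x)
}

#' @export
print.ieg_cohort <- function(x, ...) {
  cat(sprintf("<ieg_cohort> %d mice, line %s, protocol %s\n", length(x),
              x[[1]]$ieg_line, x[[1]]$schedule$protocol))
  invisible(x)
}
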