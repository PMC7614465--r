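#' Draw per-neuron ground truth for one synthetic mouse
#'
#' Assigns each neuron a functional type (visual, motor, mismatch, untuned)
#' with tuning weights, a preferred direction, a baseline firing rate, a
#' baseline expression level, and the per-condition expression drive that
#' links IEG induction to functional identity.
#'
#' Type counts are the largest-remainder rounding of
#' `type_fractions * n_neurons`. Untuned neurons have all tuning weights 0.
#' Mismatch neurons additionally carry a smaller motor weight, reflecting the
#' motor-related excitatory input they receive.
#'
#' Per-condition drives are built from `cfg$drive_map`; identical map entries
#' in different conditions share one draw, so the expression pattern only
#' re-ranks where the map changes:
#' `uniform` (all 1), `random` (iid lognormal), `visual` (follows the visual
#' weight), `visual_corridor` (visual weight gated by tuning to the vertical
#' corridor grating), `motor` (follows motor + mismatch weights). Drives are
#' scaled to mean 1.
#'
#' @param cfg an [generator_config()] object. Uses the current RNG state.
#' @return data frame, one row per neuron: `neuron`, `type`, `visual_weight`,
#'   `motor_weight`, `mismatch_weight`, `preferred_orientation`,
#'   `baseline_rate_hz`, `ieg_baseline`, `drive_c1`..`drive_c3`.
#' @export
make_ground_truth <- function(cfg) {
  n <- cfg$n_neurons_per_mouse
  counts <- .largest_remainder(cfg$type_fractions * n)
  type <- rep(names(counts), counts)[sample.int(n)]

  vw <- mw <- mmw <- numeric(n)
  gain <- function(k) abs(stats::rnorm(k, 1, 0.3))
  vw[type == "visual"] <- gain(sum(type == "visual"))
  mw[type == "motor"] <- gain(sum(type == "motor"))
  is_mm <- type == "mismatch"
  mmw[is_mm] <- abs(stats::rnorm(sum(is_mm), 1.2, 0.3))
  mw[is_mm] <- 0.3 * gain(sum(is_mm))

  pref <- stats::runif(n, 0, 360)
  base_rate <- cfg$baseline_rate_hz * stats::rlnorm(n, 0, 0.05)
  ieg_base <- pmax(0.1, 1 + cfg$ieg_baseline_cv * stats::rnorm(n))

  truth <- data.frame(neuron = seq_len(n), type = type,
                      visual_weight = vw, motor_weight = mw,
                      mismatch_weight = mmw, preferred_orientation = pref,
                      baseline_rate_hz = base_rate, ieg_baseline = ieg_base,
                      stringsAsFactors = FALSE)

  draws <- list()
  for (cond in 1:3) {
    key <- cfg$drive_map[cond]
    if (is.null(draws[[key]])) draws[[key]] <- .draw_drive(key, truth)
    truth[[paste0("drive_c", cond)]] <- draws[[key]]
  }
  truth
}

.draw_drive <- function(kind, truth) {
  n <- nrow(truth)
  base <- sub("[0-9]+$", "", kind)  # visual2 etc. = an independent redraw
  d <- switch(base,
    uniform = rep(1, n),
    random = stats::rlnorm(n, 0, 0.2),
    visual = 0.3 + truth$visual_weight + 0.1 * stats::rlnorm(n, 0, 0.5),
    visual_corridor = {
      tune <- orientation_tuning(truth$preferred_orientation, 0)
      0.3 + truth$visual_weight * (0.25 + 0.75 * tune) +
        0.1 * stats::rlnorm(n, 0, 0.5)
    },
    motor = 0.3 + truth$motor_weight + truth$mismatch_weight +
      0.1 * stats::rlnorm(n, 0, 0.5),
    stop(sprintf("unknown drive_map entry '%s'", kind), call. = FALSE)
  )
  d / mean(d)
}

#' Orientation tuning factor
#'
#' Cosine tuning on orientation (period 180 degrees), in `[0, 1]`: 1 at the
#' preferred orientation, 0 at the orthogonal one.
#'
#' @param pref_deg preferred direction(s), degrees.
#' @param stim_deg stimulus direction, degrees.
#' @return tuning factor(s) in `[0, 1]`.
#' @export
orientation_tuning <- function(pref_deg, stim_deg) {
  0.5 + 0.5 * cos(2 * (pref_deg - stim_deg) * pi / 180)
}

.largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x) - sum(fl)))
  add <- rep(0L, length(x))
  if (rem > 0) {
    add[order(x - fl, decreasing = TRUE)[seq_len(rem)]] <- 1L
  }
  stats::setNames(as.integer(fl + add), names(x))
}
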