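#' Render synthetic dual-channel frame stacks
#'
#' Paints traces into pixel frames so the extraction code has a test surface:
#' the red channel paints each ROI's activity trace value into its mask
#' (frame by frame), the green channel paints each ROI's IEG snapshot value,
#' on a constant background with optional white pixel noise. Where masks
#' overlap, painted values add.
#'
#' @param act_traces neurons x frames matrix of activity fluorescence.
#' @param ieg_values neurons x timepoints matrix of expression values (or a
#'   vector for a single snapshot).
#' @param rois ROI table (`roi_id`, `row`, `col`), ids in the row order of
#'   the trace matrices; all pixels must lie within `frame_shape`.
#' @param frame_shape `c(rows, cols)` pixels.
#' @param noise_sd pixel noise SD; default scales the trace SD by
#'   `1/snr`.
#' @param background constant background level.
#' @param snr signal-to-noise used for the default `noise_sd`.
#' @param seed integer seed for the pixel noise.
#' @return list with `red` (`rows x cols x frames`) and `green`
#'   (`rows x cols x timepoints`) arrays.
#' @export
render_frames <- function(act_traces, ieg_values, rois,
                          frame_shape = c(60L, 80L), noise_sd = NULL,
                          background = 0, snr = 10, seed = 1L) {
  if (is.vector(ieg_values)) ieg_values <- matrix(ieg_values, ncol = 1)
  if (nrow(rois) > 0) .check_rois(rois, frame_shape)
  ids <- unique(rois$roi_id)
  if (length(ids) > 0 &&
      (length(ids) != nrow(act_traces) || length(ids) != nrow(ieg_values))) {
    stop("ROI count must match trace rows", call. = FALSE)
  }
  if (is.null(noise_sd)) {
    noise_sd <- if (snr > 0) stats::sd(act_traces) / snr else 0
    if (!is.finite(noise_sd)) noise_sd <- 0
  }
  red <- .paint(act_traces, rois, ids, frame_shape, background)
  green <- .paint(ieg_values, rois, ids, frame_shape, background)
  if (noise_sd > 0) {
    with_seed(seed, {
      red <- red + array(stats::rnorm(length(red), 0, noise_sd), dim(red))
      green <- green + array(stats::rnorm(length(green), 0, noise_sd),
                             dim(green))
    })
  }
  list(red = red, green = green)
}

.paint <- function(values, rois, ids, shape, background) {
  nf <- ncol(values)
  out <- array(background, dim = c(shape[1], shape[2], max(nf, 0)))
  if (nf == 0 || length(ids) == 0) return(out)
  pix <- (rois$col - 1L) * shape[1] + rois$row
  grp <- match(rois$roi_id, ids)
  flat <- matrix(out, nrow = shape[1] * shape[2])
  for (i in seq_along(ids)) {
    p <- pix[grp == i]
    flat[p, ] <- flat[p, ] + rep(values[i, ], each = length(p))
  }
  array(flat, dim = dim(out))
}

#' Disk-shaped ROI masks on a grid
#'
#' Convenience generator of non-overlapping circular ROI masks for rendering
#' tests and synthetic exports.
#'
#' @param n number of ROIs.
#' @param frame_shape `c(rows, cols)` pixels.
#' @param radius disk radius in pixels.
#' @return ROI table (`roi_id`, `row`, `col`).
#' @export
make_roi_grid <- function(n, frame_shape = c(60L, 80L), radius = 2) {
  step <- 2 * radius + 3
  rows <- seq(radius + 2, frame_shape[1] - radius - 1, by = step)
  cols <- seq(radius + 2, frame_shape[2] - radius - 1, by = step)
  centers <- expand.grid(row = rows, col = cols)
  if (nrow(centers) < n) stop("frame too small for requested ROI count")
  centers <- centers[seq_len(n), ]
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(roi_id = i, row = centers$row[i] + off$dr,
               col = centers$col[i] + off$dc)
  }))
}
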