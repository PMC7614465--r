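#' Extract ROI fluorescence traces from a frame stack
#'
#' The trace of an ROI in a frame is the arithmetic mean of the pixel values
#' inside its mask. Channel convention throughout the package: channel 1 =
#' red / calcium activity, channel 2 = green / IEG reporter. Pixel
#' coordinates are 1-based (R convention).
#'
#' @param stack numeric array `rows x cols x frames` (a single frame may be
#'   passed as a matrix).
#' @param rois ROI table: data frame with `roi_id`, `row`, `col`, one row per
#'   mask pixel. Every ROI must have at least one pixel and all pixels must
#'   lie inside the frame.
#' @return numeric matrix, ROIs x frames, rownames = ROI ids (sorted by
#'   first appearance).
#' @export
extract_roi_fluorescence <- function(stack, rois) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3)
  .check_rois(rois, dim(stack)[1:2])
  nf <- dim(stack)[3]
  ids <- unique(rois$roi_id)
  flat <- matrix(stack, nrow = prod(dim(stack)[1:2]), ncol = nf)
  pix <- (rois$col - 1L) * dim(stack)[1] + rois$row
  out <- matrix(NA_real_, length(ids), nf, dimnames = list(ids, NULL))
  grp <- match(rois$roi_id, ids)
  for (i in seq_along(ids)) {
    p <- pix[grp == i]
    out[i, ] <- if (length(p) == 1L) flat[p, ] else colMeans(flat[p, , drop = FALSE])
  }
  out
}

.check_rois <- function(rois, shape) {
  req <- c("roi_id", "row", "col")
  if (!all(req %in% names(rois))) {
    stop("ROI table needs columns roi_id, row, col", call. = FALSE)
  }
  if (nrow(rois) == 0) stop("empty ROI table", call. = FALSE)
  if (any(rois$row < 1 | rois$row > shape[1] |
            rois$col < 1 | rois$col > shape[2])) {
    stop("ROI mask pixel outside frame bounds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Median-normalized dF/F
#'
#' `dff[i, t] = (F[i, t] - median_t F[i, .]) / median_t F[i, .]`, the
#' per-neuron median taken over the samples of the matrix passed in (i.e. per
#' recording segment when called segment-wise). Optionally followed by a
#' causal exponentially weighted smoothing filter with time constant
#' `filter_tau_s`. Negative dF/F is preserved (no rectification). Neurons
#' whose median fluorescence is not strictly positive cannot be normalized;
#' they are excluded (rows set to `NA`) and listed in the `"excluded"`
#' attribute.
#'
#' @param raw numeric matrix, neurons x samples (raw fluorescence).
#' @param rate_hz sampling rate of the trace grid (Hz).
#' @param filter_tau_s smoothing time constant in seconds; `0` or `NA`
#'   disables filtering.
#' @return matrix of the same shape, dF/F units, with attribute `"excluded"`
#'   (integer row indices of excluded neurons, possibly empty).
#' @export
compute_dff <- function(raw, rate_hz = 10, filter_tau_s = 0.2) {
  stopifnot(is.matrix(raw))
  med <- apply(raw, 1, stats::median)
  bad <- which(!(med > 0) | !is.finite(med))
  dff <- (raw - med) / med
  if (length(bad)) {
    dff[bad, ] <- NA_real_
    warning(sprintf("%d neuron(s) with non-positive median excluded from dF/F",
                    length(bad)))
  }
  if (!is.na(filter_tau_s) && filter_tau_s > 0 && ncol(dff) > 1) {
    a <- 1 - exp(-1 / (rate_hz * filter_tau_s))
    for (t in seq_len(ncol(dff))[-1]) {
      dff[, t] <- (1 - a) * dff[, t - 1] + a * dff[, t]
    }
  }
  attr(dff, "excluded") <- bad
  dff
}

#' Measure IEG reporter intensity per snapshot
#'
#' For each snapshot timepoint, the green-channel stack is reduced to its
#' mean-fluorescence projection and each ROI reads out the mean mask pixel
#' value of that projection.
#'
#' @param stacks list of green-channel stacks (one per snapshot timepoint);
#'   each element an array `rows x cols x frames` or a matrix (a projection).
#' @param rois ROI table (see [extract_roi_fluorescence()]).
#' @return matrix, ROIs x timepoints (raw expression values).
#' @export
measure_ieg <- function(stacks, rois) {
  vals <- vapply(stacks, function(st) {
    if (is.matrix(st)) proj <- st
    else proj <- apply(st, c(1, 2), mean)
    extract_roi_fluorescence(proj, rois)[, 1]
  }, numeric(length(unique(rois$roi_id))))
  matrix(vals, ncol = length(stacks),
         dimnames = list(unique(rois$roi_id), NULL))
}

#' Min/median normalization of IEG expression
#'
#' Per mouse, all ROI measurements (jointly over ROIs and timepoints) are
#' shifted by the global minimum and scaled by the global median:
#' `out = (raw - min) / (median - min)`, so the normalized matrix has minimum
#' 0 and median 1. This compensates for expression-level differences between
#' reporter lines and image-quality differences between mice; cross-mouse
#' comparisons always use normalized values. The map is idempotent and
#' invariant to positive affine rescaling of the raw input.
#'
#' @param raw neurons x timepoints matrix of raw expression, or an
#'   `ieg_snapshots` object from [simulate_ieg()].
#' @return the same type, normalized; for `ieg_snapshots` the `normalized`
#'   flag is set.
#' @export
normalize_ieg <- function(raw) {
  if (inherits(raw, "ieg_snapshots")) {
    raw$values <- normalize_ieg(raw$values)
    raw$normalized <- TRUE
    return(raw)
  }
  stopifnot(is.matrix(raw), all(is.finite(raw)))
  lo <- min(raw)
  md <- stats::median(raw)
  if (md - lo <= 0) {
    stop("degenerate expression matrix: global median equals global minimum",
         call. = FALSE)
  }
  (raw - lo) / (md - lo)
}
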