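#' Read and write frame stacks as multi-page TIFF
#'
#' One file per channel; page `t` is frame `t`. Values are stored as 32-bit
#' float samples, so traces round-trip within single precision.
#'
#' @param stack numeric array `rows x cols x frames`.
#' @param path output / input file path.
#' @return `read_stack_tiff` returns the array; `write_stack_tiff` returns
#'   `path` invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3]), function(t) stack[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write / read generator configuration as YAML
#'
#' @param cfg an [generator_config()] object.
#' @param path file path.
#' @return `read_config_yaml` returns a validated `ieg_config`.
#' @export
write_config_yaml <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$type_fractions <- as.list(lst$type_fractions)  # keep names in YAML
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$type_fractions <- unlist(lst$type_fractions)
  cfg <- structure(lst, class = "ieg_config")
  validate_config(cfg)
  cfg
}

#' Export a mouse dataset to a directory of plain-text files
#'
#' Writes `config.yaml`, `ground_truth.csv`, `ieg_raw.csv` / `ieg_norm.csv`
#' (long format: neuron, timepoint_h, session, condition, value), a combined
#' `events.csv`, and per-segment `behavior_###.csv` logs. Times are seconds
#' (snapshot times in hours from experiment start); window conventions are
#' half-open `[start, end)`.
#'
#' @param mouse a `mouse_dataset`.
#' @param dir output directory (created if missing).
#' @param traces also write per-segment dF/F matrices (`traces_###.csv`,
#'   neurons x samples; large).
#' @return `dir`, invisibly.
#' @export
export_mouse_dataset <- function(mouse, dir, traces = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config_yaml(mouse$cfg, file.path(dir, "config.yaml"))
  utils::write.csv(mouse$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  for (what in c("ieg_raw", "ieg_norm")) {
    sn <- mouse[[what]]
    long <- data.frame(neuron = rep(seq_len(nrow(sn$values)),
                                    ncol(sn$values)),
                       timepoint_h = rep(sn$timepoint_h,
                                         each = nrow(sn$values)),
                       session = rep(sn$session, each = nrow(sn$values)),
                       condition = rep(sn$condition, each = nrow(sn$values)),
                       value = as.vector(sn$values))
    utils::write.csv(long, file.path(dir, paste0(what, ".csv")),
                     row.names = FALSE)
  }
  ev <- do.call(rbind, lapply(seq_along(mouse$segments), function(k) {
    e <- mouse$segments[[k]]$events
    if (!nrow(e)) return(NULL)
    cbind(segment = k, session = mouse$segments[[k]]$session,
          kind_segment = mouse$segments[[k]]$kind, e)
  }))
  if (!is.null(ev)) {
    utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  }
  for (k in seq_along(mouse$segments)) {
    s <- mouse$segments[[k]]
    utils::write.csv(s$behavior,
                     file.path(dir, sprintf("behavior_%03d.csv", k)),
                     row.names = FALSE)
    if (traces) {
      utils::write.csv(as.data.frame(s$dff),
                       file.path(dir, sprintf("traces_%03d.csv", k)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
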