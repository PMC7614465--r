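test_that("ROI extraction is the mask-pixel mean", {
  frame <- matrix(7, 20, 30)
  rois <- data.frame(roi_id = 1, row = c(3, 4), col = c(5, 5))
  expect_equal(as.numeric(extract_roi_fluorescence(frame, rois)), 7)
  frame[3, 5] <- 4; frame[4, 5] <- 6
  expect_equal(as.numeric(extract_roi_fluorescence(frame, rois)), 5)
  bad <- data.frame(roi_id = 1, row = 25, col = 5)
  expect_error(extract_roi_fluorescence(frame, bad), "outside")
  expect_error(extract_roi_fluorescence(frame, rois[0, ]), "empty")
})

test_that("extraction is linear in pixel values", {
  set.seed(1)
  a <- array(rnorm(20 * 30 * 4), c(20, 30, 4))
  b <- array(rnorm(20 * 30 * 4), c(20, 30, 4))
  rois <- make_roi_grid(4, c(20, 30), radius = 1)
  expect_equal(extract_roi_fluorescence(2 * a + 3 * b, rois),
               2 * extract_roi_fluorescence(a, rois) +
                 3 * extract_roi_fluorescence(b, rois),
               tolerance = 1e-12)
})

test_that("dF/F follows the median-normalization definition", {
  expect_equal(as.numeric(compute_dff(matrix(5, 1, 10), filter_tau_s = 0)),
               rep(0, 10))
  expect_equal(as.numeric(compute_dff(matrix(c(1, 1, 1, 2), 1),
                                      filter_tau_s = 0)),
               c(0, 0, 0, 1))
  # multiplicative gain invariance
  set.seed(2)
  f <- matrix(abs(rnorm(200, 5)), 4)
  expect_equal(compute_dff(3.7 * f), compute_dff(f), tolerance = 1e-12)
  # filter disabled equals filtering with a zero time constant
  expect_equal(compute_dff(f, filter_tau_s = 0),
               compute_dff(f, filter_tau_s = NA))
  # non-positive median excludes and flags the neuron
  f[2, ] <- -1
  expect_warning(d <- compute_dff(f), "excluded")
  expect_true(all(is.na(d[2, ])))
  expect_equal(attr(d, "excluded"), 2L)
  expect_false(anyNA(d[-2, ]))
})

test_that("IEG snapshot measurement uses the mean projection", {
  rois <- data.frame(roi_id = c(1, 1, 2), row = c(2, 3, 8), col = c(2, 2, 9))
  proj <- matrix(3, 10, 10)
  expect_equal(as.numeric(measure_ieg(list(proj), rois)), c(3, 3))
  set.seed(3)
  st <- array(rnorm(10 * 10 * 5, 10), c(10, 10, 5))
  expect_equal(measure_ieg(list(st), rois)[, 1],
               extract_roi_fluorescence(apply(st, c(1, 2), mean), rois)[, 1])
  # a single-frame stack degenerates to plain extraction
  one <- array(rnorm(100, 5), c(10, 10, 1))
  expect_equal(measure_ieg(list(one), rois)[, 1],
               extract_roi_fluorescence(one, rois)[, 1])
})

test_that("min/median normalization has the stated post-conditions", {
  expect_equal(normalize_ieg(matrix(c(2, 4, 6), 1)),
               matrix(c(0, 1, 2), 1))
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rlnorm(200 * 12), 200)
    nx <- normalize_ieg(x)
    expect_equal(min(nx), 0, tolerance = 1e-9)
    expect_equal(median(nx), 1, tolerance = 1e-9)
    # idempotent, and invariant to positive affine rescaling of the input
    expect_equal(normalize_ieg(nx), nx, tolerance = 1e-12)
    expect_equal(normalize_ieg(2.3 * x + 7), nx, tolerance = 1e-9)
  }
  expect_error(normalize_ieg(matrix(1, 5, 5)), "degenerate")
})

test_that("rendered frames round-trip through extraction", {
  set.seed(5)
  n <- 6
  traces <- matrix(abs(rnorm(n * 40, 10, 3)), n)
  ieg <- matrix(abs(rnorm(n * 3, 5)), n)
  rois <- make_roi_grid(n, c(40, 50), radius = 2)
  # noiseless: exact recovery on zero background
  fr <- render_frames(traces, ieg, rois, c(40, 50), noise_sd = 0)
  expect_equal(extract_roi_fluorescence(fr$red, rois), traces,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(measure_ieg(lapply(1:3, function(t) fr$green[, , t]), rois),
               ieg, ignore_attr = TRUE, tolerance = 1e-12)
  # empty mask set: pure background
  bg <- render_frames(traces, ieg, rois[0, ], c(40, 50), noise_sd = 0,
                      background = 0.4)
  expect_true(all(bg$red == 0.4))
  # default noise at snr 10: per-neuron round-trip correlation > 0.99
  fr2 <- render_frames(traces, ieg, rois, c(40, 50), snr = 10, seed = 2)
  rec <- extract_roi_fluorescence(fr2$red, rois)
  for (i in seq_len(n)) expect_gt(cor(rec[i, ], traces[i, ]), 0.99)
  expect_error(render_frames(traces, ieg,
                             data.frame(roi_id = 1, row = 99, col = 1),
                             c(40, 50)), "outside|match")
})

test_that("TIFF stacks and YAML configs round-trip through disk", {
  set.seed(6)
  st <- array(runif(8 * 9 * 3), c(8, 9, 3))
  path <- tempfile(fileext = ".tiff")
  write_stack_tiff(st, path)
  expect_equal(read_stack_tiff(path), st, tolerance = 1e-6)  # float32
  cfg <- fig1_cfg("EGR1")
  ypath <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, ypath)
  cfg2 <- read_config_yaml(ypath)
  expect_equal(cfg2$snr_ieg, cfg$snr_ieg)
  expect_equal(cfg2$type_fractions, cfg$type_fractions)
})

test_that("mouse datasets export to plain-text files", {
  cfg <- fig1_cfg(n_neurons = 10, n_mice = 1)
  cfg$fig1_segment_s <- 10
  m <- simulate_mouse(cfg, seed = 3, keep_fluor = FALSE)
  dir <- file.path(tempdir(), "mouse_export")
  export_mouse_dataset(m, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir, "ieg_norm.csv")))
  long <- read.csv(file.path(dir, "ieg_norm.csv"))
  expect_equal(nrow(long), 10 * 25)
  expect_equal(min(long$value), 0, tolerance = 1e-9)
})
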