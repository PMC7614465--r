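test_that("activity summaries reduce segments to the documented statistics", {
  m <- fake_mouse(list(matrix(0.4, 2, 30), matrix(c(0, 1, 0), 2, 30,
                                                  byrow = TRUE)))
  s_mean <- summarize_activity(m, "mean")
  s_max <- summarize_activity(m, "max")
  expect_equal(s_mean$values[, 1], c(0.4, 0.4))
  expect_equal(s_max$values[, 1], c(0.4, 0.4))
  expect_equal(s_mean$values[, 2], c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(s_max$values[, 2], c(1, 1))
})

test_that("pooled mean over equal-length segments equals mean of segment means", {
  set.seed(7)
  d1 <- matrix(rnorm(5 * 40), 5)
  d2 <- matrix(rnorm(5 * 40), 5)
  m <- fake_mouse(list(d1, d2))
  # both segments in one session
  m$segments[[2]]$session <- 1L
  m$ieg_raw$session <- c(1L, 1L)
  pooled <- summarize_activity(m, "mean")$values[, 1]
  expect_equal(pooled, (rowMeans(d1) + rowMeans(d2)) / 2, tolerance = 1e-12)
})

test_that("segment summary mixes mean and max convexly", {
  set.seed(8)
  d <- matrix(rnorm(30), 3)
  mx <- apply(d, 1, max)
  expect_equal(segment_activity_summary(d, 0), rowMeans(d))
  expect_equal(segment_activity_summary(d, 1), mx)
  expect_equal(segment_activity_summary(d, 0.3),
               0.7 * rowMeans(d) + 0.3 * mx)
})

test_that("lagged correlation matches its definition on canonical cases", {
  set.seed(9)
  v <- matrix(rnorm(40), 10, 4)
  act <- structure(v, timepoint_h = 0:3)
  # identical expression: r = 1 at lag 0
  cc <- lagged_population_correlation(act, v, lag_grid_h = seq(-2, 2, 0.25),
                                      timepoint_h = 0:3)
  expect_equal(cc$r[cc$lag_h == 0], 1)
  expect_equal(cc$n_pairs[cc$lag_h == 0], 4L)
  # lags with no pairs are missing, not zero
  expect_true(is.na(cc$r[cc$lag_h == 0.5]))
  # a k-step delayed copy moves the peak by +k grid steps
  ieg_del <- cbind(matrix(rnorm(20), 10, 2), v[, 1:2])
  cc2 <- lagged_population_correlation(act, ieg_del,
                                       lag_grid_h = seq(-3, 3, 1),
                                       timepoint_h = 0:3)
  expect_equal(cc2$lag_h[which.max(cc2$r)], 2)
})

test_that("lagged correlation equals the brute-force pair enumeration", {
  set.seed(10)
  for (i in 1:5) {
    na <- sample(3:5, 1); ni <- sample(3:5, 1); nn <- sample(5:10, 1)
    av <- matrix(rnorm(nn * na), nn)
    iv <- matrix(rnorm(nn * ni), nn)
    at <- sort(sample(seq(0, 3, 0.25), na))
    it <- sort(sample(seq(0, 3, 0.25), ni))
    grid <- seq(-3, 3, 0.25)
    got <- lagged_population_correlation(structure(av, timepoint_h = at), iv,
                                         grid, timepoint_h = it)
    expect_equal(got$r, brute_lagged_correlation(av, at, iv, it, grid),
                 tolerance = 1e-12)
  }
})

test_that("role reversal mirrors the lag axis", {
  set.seed(11)
  nn <- 8
  av <- matrix(rnorm(nn * 4), nn); iv <- matrix(rnorm(nn * 4), nn)
  t4 <- c(0, 0.5, 1, 2)
  grid <- seq(-2, 2, 0.25)
  fwd <- lagged_population_correlation(structure(av, timepoint_h = t4), iv,
                                       grid, timepoint_h = t4)
  bwd <- lagged_population_correlation(structure(iv, timepoint_h = t4), av,
                                       grid, timepoint_h = t4)
  expect_equal(fwd$r, bwd$r[length(grid):1], tolerance = 1e-12)
})

test_that("peak statistics use the earliest lag on ties and refine on smooth curves", {
  curve <- data.frame(lag_h = seq(-2, 6, 0.25), r = 0)
  curve$r[curve$lag_h %in% c(1, 3)] <- 0.5       # symmetric two-peak tie
  pk <- peak_statistics(list(curve))
  expect_equal(pk$per_mouse$peak_lag_h, 1)
  expect_equal(pk$per_mouse$peak_r, 0.5)
  # quadratic refinement recovers an off-grid vertex exactly
  lag <- seq(-2, 6, 0.25)
  par_curve <- data.frame(lag_h = lag, r = 0.3 - 0.05 * (lag - 3.6)^2)
  pk2 <- peak_statistics(list(par_curve))
  expect_equal(pk2$per_mouse$peak_lag_refined_h, 3.6, tolerance = 1e-9)
  expect_error(peak_statistics(list(data.frame(lag_h = 1, r = NA_real_))),
               "no valid lag")
})

test_that("bootstrap group comparison behaves at its boundaries", {
  x <- c(0.2, 0.3, 0.25, 0.35)
  res <- bootstrap_t_compare(x, x, seed = 4)
  expect_gt(res$p_value, 0.05)
  expect_identical(res$p_value, bootstrap_t_compare(x, x, seed = 4)$p_value)
  expect_false(identical(res$p_value,
                         bootstrap_t_compare(x, x, seed = 5)$p_value))
  # widely separated groups
  res2 <- bootstrap_t_compare(c(0, 0.01, 0.02, 0.01), c(10, 10.01, 9.99, 10),
                              seed = 1)
  expect_lt(res2$p_value, 0.001)
  expect_warning(res3 <- bootstrap_t_compare(c(1, 1), c(1, 1), seed = 1),
                 "degenerate")
  expect_equal(res3$p_value, 1)
})

test_that("mean- vs max-mode contrast follows the generator mixture weight", {
  # identical mean and max summaries: per-neuron constant traces,
  # difference exactly 0
  const <- matrix(c(0.1, 0.2, 0.3, 0.4), 4, 20)
  m <- fake_mouse(list(const, const), ieg_values = matrix(rlnorm(8), 4))
  mm <- mean_vs_max_contrast(list(m, m))
  expect_equal(mm$per_mouse$r_max, mm$per_mouse$r_mean)
  # session-wise contrast: induction kinetics fast enough that the last
  # snapshot of a session reads out that session's own activity
  diffs <- function(w) vapply(1:8, function(seed) {
    cfg <- fig2_cfg("Arc", n_neurons = 100, coupling_mode = w,
                    induction_delay_h = 0.1, ieg_decay_h = 0.08,
                    snr_ieg = 8,
                    drive_map = c("uniform", "uniform", "uniform"))
    coh <- simulate_cohort(cfg, "learning_fig2", seed = seed,
                           keep_fluor = FALSE)
    ct <- mean_vs_max_contrast(coh)
    ct$per_mouse$r_max[1] - ct$per_mouse$r_mean[1]
  }, numeric(1))
  # pure max drive (w = 1): max-mode correlation wins in nearly all seeds
  expect_gte(mean(diffs(1) > 0), 7 / 8)
  # pure mean drive (w = 0): the max mode has no advantage
  expect_lte(mean(diffs(0) > 0), 0.5)
})
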