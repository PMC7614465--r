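test_that("running-onset detection obeys threshold, quiescence and duration", {
  t_s <- seq(0, 60, by = 0.1)
  quiet <- data.frame(time_s = t_s, running_speed = 0)
  expect_equal(nrow(detect_running_onsets(quiet)), 0)
  step <- data.frame(time_s = t_s,
                     running_speed = ifelse(t_s >= 10 & t_s < 13, 5, 0))
  on <- detect_running_onsets(step, threshold = 1, quiet_s = 1, run_s = 1)
  expect_equal(on$time_s, 10)
  # a bout too short to satisfy the sustained-running requirement is ignored
  blip <- data.frame(time_s = t_s,
                     running_speed = ifelse(t_s >= 10 & t_s < 10.5, 5, 0))
  expect_equal(nrow(detect_running_onsets(blip, run_s = 1)), 0)
  # quiescence requirement: a second crossing shortly after running ends
  double <- data.frame(time_s = t_s,
                       running_speed = ifelse((t_s >= 10 & t_s < 13) |
                                                (t_s >= 13.3 & t_s < 16), 5, 0))
  expect_equal(detect_running_onsets(double)$time_s, 10)
})

test_that("detected onsets track the generator's true bout onsets", {
  cfg <- fig1_cfg(rest_dwell_s = 20, run_dwell_s = 10, fig1_segment_s = 600)
  sch <- build_schedule("learning_fig2", cfg, n_sessions = 2)
  det <- tru <- 0
  for (seed in 1:5) {
    segs <- simulate_behavior(sch, cfg, seed)
    for (s in segs) {
      det <- det + nrow(detect_running_onsets(s$behavior,
                                              rate_hz = cfg$trace_rate_hz))
      tru <- tru + sum(s$events$kind == "run_onset_true")
    }
  }
  expect_gt(tru, 20)
  expect_lte(det, tru)              # detection criteria are stricter
  expect_gt(det, 0.5 * tru)         # but catch most sustained bouts
})

test_that("event-triggered responses are baseline-subtracted window means", {
  t_s <- seq(0, 20, by = 0.1)
  flat <- matrix(0.7, 2, length(t_s))
  r <- event_triggered_response(flat, t_s, c(5, 10))
  expect_equal(r$mean_response, c(0, 0))
  expect_equal(r$n_events, 2L)
  stepm <- matrix(rep(ifelse(t_s >= 10, 1, 0), each = 2), 2)
  r2 <- event_triggered_response(stepm, t_s, 10)
  expect_equal(r2$mean_response, c(1, 1))
  # events with truncated windows are dropped and counted
  r3 <- event_triggered_response(stepm, t_s, c(0.2, 19.9, 10))
  expect_equal(r3$n_events, 1L)
  expect_equal(r3$n_dropped, 2L)
  r4 <- event_triggered_response(stepm, t_s, numeric(0))
  expect_equal(r4$n_events, 0L)
  expect_true(all(is.na(r4$mean_response)))
})

test_that("event-triggered averages of unlocked traces shrink to zero", {
  set.seed(16)
  t_s <- seq(0, 300, by = 0.1)
  dff <- matrix(rnorm(length(t_s) * 3, 0, 0.2), 3)
  ev <- sort(runif(40, 5, 295))
  r <- event_triggered_response(dff, t_s, ev)
  se <- 0.2 * sqrt(1 / 15 + 1 / 4) / sqrt(r$n_events)
  expect_true(all(abs(r$mean_response) < 3 * se + 0.02))
})

test_that("population z-scores standardize and preserve order", {
  expect_equal(zscore_over_population(c(-1, 1)), c(-1, 1))
  set.seed(17)
  x <- rnorm(50, 3, 2)
  z <- zscore_over_population(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)
  expect_equal(zscore_over_population(5 * x + 2), z, tolerance = 1e-9)
  expect_error(zscore_over_population(rep(1, 10)), "zero standard deviation")
  expect_error(zscore_over_population(3), ">= 2")
})

test_that("top-decile selection reproduces printed cohort counts", {
  set.seed(18)
  for (spec in list(c(1969, 197), c(1213, 121), c(1885, 189))) {
    vals <- matrix(rlnorm(spec[1] * 2), spec[1])
    expect_length(select_high_ieg(vals, fraction = 0.10), spec[2])
  }
  # N = 10: the single highest expresser
  v10 <- matrix(c(1:9, 100), 10, 1)
  expect_equal(select_high_ieg(v10, fraction = 0.10), 10L)
  # selected minimum dominates unselected maximum
  v <- matrix(rnorm(500), 500)
  sel <- select_high_ieg(v, fraction = 0.1)
  expect_gte(min(v[sel, 1]), max(v[-sel, 1]))
  expect_error(select_high_ieg(v, fraction = 0), "fraction")
  expect_error(select_high_ieg(v, fraction = 1.2), "fraction")
})

test_that("behavior correlations recover constructed relationships", {
  set.seed(19)
  t_n <- 400
  run <- abs(rnorm(t_n, 5, 2))
  flow <- abs(rnorm(t_n, 5, 2))
  dff <- rbind(run, rnorm(t_n))
  m <- fake_mouse(list(dff), kind = "open_loop", condition = 2L)
  m$segments[[1]]$behavior$running_speed <- run
  m$segments[[1]]$behavior$visual_flow <- flow
  bc <- behavior_correlations(m)
  expect_equal(bc$r_running[1], 1, tolerance = 1e-9)
  expect_lt(abs(bc$r_running[2]), 3 / sqrt(t_n))
  expect_lt(abs(bc$r_flow[2]), 3 / sqrt(t_n))
  # constant behavior trace is marked missing
  m$segments[[1]]$behavior$visual_flow <- 1
  expect_true(all(is.na(behavior_correlations(m)$r_flow)))
  expect_error(behavior_correlations(fake_mouse(list(dff))), "open-loop")
})

test_that("group contrasts report the documented tests", {
  set.seed(20)
  vals <- rnorm(200)
  grp <- 1:20
  gc0 <- group_contrast(vals, grp)
  expect_s3_class(gc0$vs_rest, "TestResult")
  vals_shift <- vals; vals_shift[grp] <- vals_shift[grp] + 10
  gc <- group_contrast(vals_shift, grp)
  expect_lt(gc$vs_rest$p_value, 0.001)
  expect_lt(gc$vs_zero$p_value, 0.001)
  expect_equal(gc$group_mean - gc$rest_mean, 10, tolerance = 0.5)
  # all-zero values: degenerate tests are skipped, means still reported
  gz <- group_contrast(rep(0, 50), 1:5)
  expect_null(gz$vs_zero)
  expect_null(gz$vs_rest)
  expect_equal(gz$group_mean, 0)
})
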