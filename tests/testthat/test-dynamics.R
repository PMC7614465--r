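test_that("timecourses average neurons within sessions", {
  m1 <- fake_mouse(list(matrix(0.5, 1, 20), matrix(0.5, 1, 20)))
  tc <- build_timecourse(list(m1), "activity")
  expect_equal(tc$value, c(0.5, 0.5))
  m2 <- fake_mouse(list(rbind(rep(0, 20), rep(1, 20))))
  expect_equal(build_timecourse(list(m2), "activity")$value, 0.5)
  # ieg timecourse takes the session's last snapshot of normalized expression
  m3 <- fake_mouse(list(matrix(0, 2, 10), matrix(0, 2, 10)),
                   ieg_values = cbind(c(1, 3), c(2, 6)))
  tci <- build_timecourse(list(m3), "ieg")
  expect_equal(tci$value, colMeans(m3$ieg_norm$values))
})

test_that("condition-boundary change uses two-session windows on each side", {
  tc <- data.frame(mouse = 1, session = 1:8, timepoint_h = (1:8) * 12,
                   condition = rep(c(2, 3), each = 4),
                   value = c(1, 1, 1, 1, 3, 3, 3, 3))
  class(tc) <- c("timecourse_table", "data.frame")
  ch <- condition_change(tc, c(2, 3))
  expect_equal(ch$per_mouse$change, 2)
  # constant timecourse: zero change
  tc$value <- 5
  expect_equal(condition_change(tc, c(2, 3))$per_mouse$change, 0)
})

test_that("condition change is shift-invariant and scale-equivariant", {
  set.seed(12)
  tc <- data.frame(mouse = rep(1:3, each = 8), session = rep(1:8, 3),
                   timepoint_h = rep((1:8) * 12, 3),
                   condition = rep(rep(c(2, 3), each = 4), 3),
                   value = rnorm(24))
  class(tc) <- c("timecourse_table", "data.frame")
  base <- condition_change(tc, c(2, 3))
  shifted <- tc; shifted$value <- shifted$value + 11
  scaled <- tc; scaled$value <- scaled$value * 3
  expect_equal(condition_change(shifted, c(2, 3))$per_mouse$change,
               base$per_mouse$change, tolerance = 1e-12)
  expect_equal(condition_change(scaled, c(2, 3))$per_mouse$change,
               3 * base$per_mouse$change, tolerance = 1e-12)
})

test_that("an injected expression step is recovered by the change statistic", {
  set.seed(13)
  step <- 0.8
  changes <- replicate(10, {
    vals <- lapply(1:4, function(m) c(rnorm(8, 1, 0.1),
                                      rnorm(4, 1 + step, 0.1)))
    tc <- data.frame(mouse = rep(1:4, each = 12), session = rep(1:12, 4),
                     timepoint_h = rep((1:12) * 12, 4),
                     condition = rep(rep(1:3, each = 4), 4),
                     value = unlist(vals))
    class(tc) <- c("timecourse_table", "data.frame")
    condition_change(tc, c(2, 3))$mean_change
  })
  expect_lt(abs(mean(changes) - step), 2 * sd(changes) / sqrt(10) + 0.05)
})

test_that("linear trend reports OLS slope, R2 and F-test", {
  tc <- data.frame(mouse = 1, session = 1:6, timepoint_h = 1:6,
                   condition = 2, value = 2 * (1:6) + 1)
  class(tc) <- c("timecourse_table", "data.frame")
  lt <- linear_trend(tc, 2)
  expect_equal(lt$slope, 2, tolerance = 1e-9)
  expect_equal(lt$r_squared, 1, tolerance = 1e-9)
  expect_equal(lt$mean_fit[["slope"]], 2, tolerance = 1e-9)
  expect_error(linear_trend(tc[1:2, ], 2), ">= 3")
})

test_that("white-noise timecourses give calibrated trend p-values", {
  set.seed(14)
  ps <- replicate(150, {
    tc <- data.frame(mouse = rep(1:3, each = 8), session = rep(1:8, 3),
                     timepoint_h = rep(1:8, 3), condition = 2,
                     value = rnorm(24))
    class(tc) <- c("timecourse_table", "data.frame")
    linear_trend(tc, 2)$test$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(median(replicate(50, {
    tc <- data.frame(mouse = 1, session = 1:10, timepoint_h = 1:10,
                     condition = 2, value = rnorm(10))
    class(tc) <- c("timecourse_table", "data.frame")
    linear_trend(tc, 2)$r_squared
  })), 0.35)
})

test_that("pattern similarity is a rank statistic with unit diagonal", {
  v <- cbind(c(1, 2, 3, 4), c(10, 20, 30, 40), c(4, 3, 2, 1))
  s <- pattern_similarity(list(v))
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], -1)
  expect_equal(diag(s), rep(1, 3))
  # invariant under strictly monotone transforms
  expect_equal(pattern_similarity(list(exp(v))), s, tolerance = 1e-12)
  # constant timepoint is marked missing
  v2 <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5))
  s2 <- pattern_similarity(list(v2))
  expect_true(all(is.na(s2[, 2])))
  expect_equal(s2[1, 1], 1)
  # equals Spearman via explicit ranks (oracle)
  set.seed(15)
  v3 <- matrix(rnorm(40), 8)
  expect_equal(pattern_similarity(list(v3)),
               stats::cor(apply(v3, 2, rank)), tolerance = 1e-10)
  expect_error(pattern_similarity(list(matrix(1:4, 2))), ">= 2 timepoints|neurons")
})

test_that("learning-protocol expression dynamics show the line-specific steps", {
  arc <- simulate_cohort(fig2_cfg("Arc", n_mice = 2), "learning_fig2",
                         seed = 7, keep_fluor = FALSE)
  egr <- simulate_cohort(fig2_cfg("EGR1", n_mice = 2), "learning_fig2",
                         seed = 7, keep_fluor = FALSE)
  ch_arc <- condition_change(build_timecourse(arc, "ieg"), c(2, 3))
  ch_egr <- condition_change(build_timecourse(egr, "ieg"), c(2, 3))
  expect_gt(ch_arc$mean_change, 0.3)   # expression steps up at condition 3
  expect_lt(ch_egr$mean_change, -0.1)  # and down for EGR1
  # EGR1 pattern re-ranks at condition-3 onset: within-condition similarity
  # exceeds similarity across the boundary
  s <- pattern_similarity(egr)
  within <- mean(c(s[5:8, 5:8][upper.tri(diag(4))],
                   s[9:12, 9:12][upper.tri(diag(4))]))
  across <- mean(s[5:8, 9:12])
  expect_gt(within, across + 0.1)
})
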