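test_that("sine fit is exact on noiseless signals", {
  fs <- 1000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- vor_trace(10 * sin(2 * pi * tt), fs)
  f <- fit_sine(x, 1)
  expect_equal(f$amplitude, 10, tolerance = 1e-10)
  expect_equal(f$phase, 0, tolerance = 1e-8)
  expect_equal(f$offset, 0, tolerance = 1e-10)

  # adding a constant changes only the offset
  f3 <- fit_sine(vor_trace(10 * sin(2 * pi * tt) + 3, fs), 1)
  expect_equal(f3$offset, 3, tolerance = 1e-10)
  expect_equal(f3$amplitude, 10, tolerance = 1e-10)

  expect_error(fit_sine(vor_trace(sin(2 * pi * tt[1:500]), fs), 1),
               "two cycles")
})

test_that("sine fit tolerates gaps and noise at the OLS rate", {
  set.seed(14)
  fs <- 1000
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  y <- 10 * sin(2 * pi * tt) + stats::rnorm(length(tt), 0, 1)
  y[sample(length(y), 0.2 * length(y))] <- NA  # 20% gap-marked
  f <- fit_sine(vor_trace(y, fs), 1)
  n_ok <- sum(!is.na(y))
  se <- 1 * sqrt(2 / n_ok)
  expect_lt(abs(f$amplitude - 10), 3 * se)
  expect_equal(f$residual_rms, 1, tolerance = 0.05)
})

test_that("gain is the eye/head amplitude ratio", {
  fs <- 1000
  tt <- seq(0, 5 - 1 / fs, by = 1 / fs)
  eye <- fit_sine(vor_trace(8 * sin(2 * pi * tt + pi), fs), 1)
  head <- fit_sine(vor_trace(10 * sin(2 * pi * tt), fs), 1)
  g <- compute_gain(eye, head)
  expect_equal(g$gain, 0.8, tolerance = 1e-10)
  expect_equal(abs(g$phase_diff), 180, tolerance = 1e-6)
  expect_equal(compute_gain(head, head)$gain, 1)
  flat <- fit_sine(vor_trace(rep(0, length(tt)) + 1e-15 * tt, fs), 1)
  expect_error(compute_gain(eye, flat), "amplitude")
})

test_that("gain is invariant to a common rescaling of eye and head", {
  s <- generate_mouse_session(mouse_sim_config(true_gain = 0.6, seed = 3))
  g1 <- measure_vor_gain(s)$gain
  s2 <- s
  s2$eye_pos$values <- 2.5 * s2$eye_pos$values
  s2$head_pos$values <- 2.5 * s2$head_pos$values
  g2 <- measure_vor_gain(s2)$gain
  expect_equal(g2, g1, tolerance = 1e-12)
})

test_that("noiseless sessions give exact downstream gain recovery", {
  s <- generate_mouse_session(mouse_sim_config(true_gain = 0.8, noise_sd = 0,
                                               saccade_rate = 0, seed = 2))
  expect_equal(measure_vor_gain(s)$gain, 0.8, tolerance = 1e-6)
})

test_that("learning is the percent change in gain from baseline", {
  lc <- learning_curve(list(0.8, 1.0, 0.6), 0.8)
  expect_equal(lc$percent_change, c(0, 25, -25))
  expect_error(learning_curve(list(1), 0), "positive")
})

test_that("condition comparison gates on normality and handles degeneracy", {
  set.seed(8)
  same <- rep(5, 8)
  r <- compare_conditions(c(same, same), rep(c("a", "b"), each = 8),
                          design = "two_group")
  expect_equal(r$p, 1)

  pos <- 20 + stats::rnorm(10, 0, 1)
  r1 <- compare_conditions(pos, design = "one_sample")
  expect_equal(r1$path, "parametric")
  expect_lt(r1$p, 1e-6)

  # strongly skewed data must take the non-parametric path
  skew <- stats::rexp(20)^3
  r2 <- compare_conditions(c(skew, skew + 0.1),
                           rep(c("a", "b"), each = 20), design = "two_group")
  expect_equal(r2$path, "nonparametric")
  expect_match(r2$test, "Mann-Whitney")

  # multi-group with a clear effect, parametric path with Dunnett post-hoc
  vals <- c(stats::rnorm(8, 0), stats::rnorm(8, 0), stats::rnorm(8, 5))
  grp <- rep(c("ctrl", "g1", "g2"), each = 8)
  r3 <- compare_conditions(vals, grp, design = "multi_group", control = "ctrl")
  expect_lt(r3$p, 0.01)
  if (!is.null(r3$posthoc)) {
    expect_lt(r3$posthoc$p[r3$posthoc$group == "g2"], 0.05)
    expect_gt(r3$posthoc$p[r3$posthoc$group == "g1"], 0.05)
  }

  # repeated measures: strong within-subject condition effect
  id <- rep(1:6, times = 3)
  cond <- rep(c("pre", "post", "late"), each = 6)
  vv <- stats::rnorm(18, 0, 0.5) + ifelse(cond == "post", 4, 0)
  r4 <- compare_conditions(vv, cond, design = "repeated_measures", subject = id)
  expect_lt(r4$p, 0.01)
})

test_that("full mouse pipeline recovers gains through filtering and desaccading", {
  for (g in c(0.3, 1.0)) {
    s <- generate_mouse_session(mouse_sim_config(true_gain = g, noise_sd = 1,
                                                 saccade_rate = 1, seed = 77))
    est <- measure_vor_gain(s)$gain
    expect_lt(abs(est - g), 0.02)
  }
})
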