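test_that("pulse stimulus has the configured plateau, ramps and spacing", {
  cfg <- monkey_sim_config(n_trials_per_direction = 6, pulse_durations = 0.25,
                           seed = 3)
  stim <- make_pulse_stimulus(cfg)
  expect_equal(max(stim$head$values), 15)
  expect_equal(min(stim$head$values), -15)
  # ramp slope 600 deg/s^2 = 15 deg/s over 25 ms
  slopes <- diff(stim$head$values) * cfg$sample_rate
  expect_equal(max(slopes), 600, tolerance = 1e-6)
  # same-direction onsets spaced exactly 2.192 s, both directions
  for (dir in c("ipsiversive", "contraversive")) {
    on <- stim$trials$onset[stim$trials$direction == dir]
    expect_equal(diff(on), rep(2.192, length(on) - 1))
  }
  # zero velocity between trials
  expect_true(any(stim$head$values == 0))
})

test_that("degenerate and invalid pulse configurations are handled", {
  empty <- make_pulse_stimulus(monkey_sim_config(n_trials_per_direction = 0))
  expect_equal(nrow(empty$trials), 0)
  expect_equal(length(empty$head$values), 0)
  expect_error(monkey_sim_config(pulse_durations = c(0.25, -1)), "positive")
  expect_error(monkey_sim_config(cs_prob_in_window = 1.5), "0, 1")
  expect_error(monkey_sim_config(plasticity_persistence = -0.1), "persistence")
})

test_that("sine stimulus matches its closed form", {
  cfg <- mouse_sim_config(duration = 10, seed = 0)
  head <- make_sine_stimulus(cfg)
  expect_equal(head$values[1], 0)          # sin(0)
  expect_equal(max(abs(head$values)), 10, tolerance = 1e-4)
  # RMS over whole cycles
  expect_equal(sqrt(mean(head$values^2)), 10 / sqrt(2), tolerance = 1e-3)
  expect_error(mouse_sim_config(duration = 1.5), "two stimulus cycles")
})

test_that("sessions are deterministic in (config, seed)", {
  cfg <- monkey_sim_config(n_trials_per_direction = 10, plasticity_delta = -4,
                           seed = 11)
  s1 <- generate_monkey_session(cfg)
  s2 <- generate_monkey_session(cfg)
  expect_identical(s1$ss$times, s2$ss$times)
  expect_identical(s1$cs$times, s2$cs$times)
  expect_identical(s1$eye$values, s2$eye$values)
  s3 <- generate_monkey_session(monkey_sim_config(n_trials_per_direction = 10,
                                                  plasticity_delta = -4,
                                                  seed = 12))
  expect_false(identical(s1$ss$times, s3$ss$times))

  m1 <- generate_mouse_session(mouse_sim_config(seed = 5))
  m2 <- generate_mouse_session(mouse_sim_config(seed = 5))
  expect_identical(m1$eye_pos$values, m2$eye_pos$values)
})

test_that("window CS counts match the ground-truth flags exactly", {
  cfg <- monkey_sim_config(n_trials_per_direction = 50, cs_prob_in_window = 0.4,
                           cs_baseline_rate = 2, seed = 21)
  s <- generate_monkey_session(cfg)
  flagged <- flag_cs_in_window(s$trials, s$cs)
  expect_identical(flagged$cs_in_window, s$ground_truth$trials$cs_in_window)
  # off-direction trials never carry an in-window CS
  off <- !s$ground_truth$trials$on_direction
  expect_false(any(flagged$cs_in_window[off]))
})

test_that("degenerate CS probabilities behave as stated", {
  s1 <- generate_monkey_session(
    monkey_sim_config(n_trials_per_direction = 20, cs_prob_in_window = 1,
                      seed = 2))
  gt <- s1$ground_truth$trials
  expect_true(all(gt$cs_in_window[gt$on_direction]))
  s0 <- generate_monkey_session(
    monkey_sim_config(n_trials_per_direction = 20, cs_prob_in_window = 0,
                      plasticity_delta = -8, seed = 2))
  expect_false(any(s0$ground_truth$trials$cs_in_window))
  expect_true(all(s0$ground_truth$trials$implanted_offset == 0))
})

test_that("realized window-CS fraction obeys the binomial bound", {
  p <- 0.5
  s <- generate_monkey_session(
    monkey_sim_config(n_trials_per_direction = 1000, cs_prob_in_window = p,
                      ss_baseline_rate = 10, cs_baseline_rate = 0, seed = 33))
  gt <- s$ground_truth$trials
  frac <- mean(gt$cs_in_window[gt$on_direction])
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("implanted offsets follow CS trials of the same direction only", {
  for (pers in c(0, 0.5, 1)) {
    cfg <- monkey_sim_config(n_trials_per_direction = 60,
                             cs_prob_in_window = 0.3, plasticity_delta = -8,
                             plasticity_persistence = pers, seed = 4)
    gt <- generate_monkey_session(cfg)$ground_truth$trials
    on <- gt[gt$on_direction, ]
    # reference recursion: state after trial k feeds trial k+1
    state <- 0
    for (k in seq_len(nrow(on))) {
      expect_equal(on$implanted_offset[k], state)
      state <- state * pers + (-8) * on$cs_in_window[k]
    }
    expect_true(all(gt$implanted_offset[!gt$on_direction] == 0))
    if (pers == 0) {
      after_cs <- c(FALSE, utils::head(on$cs_in_window, -1))
      expect_identical(on$implanted_offset != 0, after_cs & TRUE)
    }
  }
})

test_that("null-session firing rate matches the configured mean", {
  cfg <- monkey_sim_config(n_trials_per_direction = 100, ss_modulation = 0,
                           cs_prob_in_window = 0, cs_baseline_rate = 0,
                           plasticity_delta = 0, seed = 8)
  s <- generate_monkey_session(cfg)
  dur <- length(s$head$values) / s$sample_rate
  n <- length(s$ss$times)
  rate <- n / dur
  se <- sqrt(n / cfg$ss_gamma_shape) / dur  # renewal count SD ~ sqrt(N*CV^2)
  expect_lt(abs(rate - 71), 3 * se + 0.5)
})

test_that("mouse ground truth propagates and gain 0 leaves only noise", {
  s <- generate_mouse_session(mouse_sim_config(true_gain = 0, saccade_rate = 0,
                                               noise_sd = 0.5, seed = 6))
  expect_equal(s$ground_truth$gain, 0)
  expect_lt(stats::sd(s$eye$values), 1)    # no stimulus-locked component
  expect_lt(abs(stats::cor(s$eye$values, s$head$values)), 0.05)
})
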