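test_that("reciprocal-interval rate matches closed forms", {
  fs <- 1000
  grid <- vor_trace(numeric(2 * fs), fs)
  # regular 10 ms train -> 100 sp/s between first and last spike
  reg <- spike_train(seq(0.1, 1.9, by = 0.01))
  r <- reciprocal_interval_rate(reg, grid)
  inside <- trace_times(grid) > 0.1 & trace_times(grid) <= 1.9
  expect_true(all(abs(r$values[inside] - 100) < 1e-9))
  expect_true(all(is.na(r$values[!inside])))

  # two spikes at {0, 0.5}: 2 sp/s on (0, 0.5]
  r2 <- reciprocal_interval_rate(spike_train(c(0, 0.5)), grid)
  tt <- trace_times(grid)
  expect_true(all(r2$values[tt > 0 & tt <= 0.5] == 2, na.rm = TRUE))
  expect_true(is.na(r2$values[1]))  # t = 0 is before/at the first spike

  # < 2 spikes: all gap
  expect_true(all(is.na(reciprocal_interval_rate(spike_train(0.3), grid)$values)))
})

test_that("rate step-function time average telescopes to (N-1)/span", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    times <- sort(stats::runif(n, 0, 50))
    iv <- reciprocal_rate_intervals(times)
    avg <- sum(iv$rate * (iv$end - iv$start)) / (max(times) - min(times))
    expect_equal(avg, (n - 1) / (max(times) - min(times)), tolerance = 1e-12)
  }
})

test_that("rate estimation is invariant to time translation", {
  set.seed(7)
  times <- sort(stats::runif(40, 0, 10))
  fs <- 500
  g1 <- vor_trace(numeric(10 * fs), fs, t0 = 0)
  g2 <- vor_trace(numeric(10 * fs), fs, t0 = 100)
  r1 <- reciprocal_interval_rate(spike_train(times), g1)
  r2 <- reciprocal_interval_rate(spike_train(times + 100), g2)
  expect_equal(r1$values, r2$values)
})

test_that("moving-baseline subtraction removes slow structure only", {
  fs <- 100
  n <- 60 * fs
  const <- vor_trace(rep(71, n), fs, unit = "sp/s")
  expect_true(all(abs(subtract_moving_baseline(const)$values) < 1e-9))

  # slow linear drift: interior residual ~ 0
  drift <- vor_trace(50 + 0.3 * seq_len(n) / fs, fs)
  res <- subtract_moving_baseline(drift)$values
  interior <- (10 * fs):(50 * fs)
  expect_lt(max(abs(res[interior])), 1e-6)

  # brief dip on constant background survives subtraction; the dip leaks
  # into the 10 s baseline by its duty fraction (51/1001 of -8 ~ 0.41)
  dip <- rep(71, n); dip[3000:3050] <- 63
  res2 <- subtract_moving_baseline(vor_trace(dip, fs))$values
  expect_equal(min(res2), -8, tolerance = 0.06)

  expect_error(subtract_moving_baseline(vor_trace(rep(1, 100), fs)), "longer")
})

test_that("CS probability histogram counts per trial and conserves spikes", {
  trials <- data.frame(onset = c(0, 2.192, 4.384, 6.576))
  # one CS at +100 ms on every trial
  cs <- spike_train(trials$onset + 0.1, "complex")
  h <- cs_probability_histogram(trials, cs, bin = 0.05)
  expect_equal(h$probability[h$bin_start == 0.10], 1)
  expect_equal(sum(h$probability), 1)

  h0 <- cs_probability_histogram(trials, spike_train(numeric(0), "complex"))
  expect_true(all(h0$probability == 0))
  expect_error(cs_probability_histogram(trials[0, , drop = FALSE], cs), "trial")

  # conservation: sum(prob * n_trials) = number of in-span CS
  set.seed(1)
  cs2 <- spike_train(sort(stats::runif(30, 0, 7)), "complex")
  h2 <- cs_probability_histogram(trials, cs2, bin = 0.05, span = c(0, 0.5))
  n_in <- sum(vapply(trials$onset, function(on)
    sum(cs2$times >= on & cs2$times < on + 0.5), numeric(1)))
  expect_equal(sum(h2$probability) * nrow(trials), n_in)
})

test_that("binned CS probability estimates a Bernoulli rate", {
  set.seed(9)
  p <- 0.3
  onsets <- (0:499) * 2.192
  hit <- stats::runif(500) < p
  cs <- spike_train(onsets[hit] + 0.12, "complex")
  h <- cs_probability_histogram(data.frame(onset = onsets), cs, bin = 0.05)
  est <- h$probability[h$bin_start == 0.10]
  expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / 500))
})

test_that("post-CS pause is the latency to the next simple spike", {
  ss <- spike_train(c(0.5, 1.015, 1.4), "simple")
  cs <- spike_train(c(1.0, 2.0), "complex")
  res <- post_cs_pause(cs, ss)
  expect_equal(res$pauses, 0.015)           # CS after last SS excluded
  expect_equal(res$cs_times, 1.0)

  empty <- post_cs_pause(cs, spike_train(numeric(0), "simple"))
  expect_equal(length(empty$pauses), 0)

  # generator respects the configured pause
  s <- generate_monkey_session(
    monkey_sim_config(n_trials_per_direction = 40, cs_prob_in_window = 0.5,
                      pause_duration = 0.020, seed = 12))
  expect_gte(post_cs_pause(s$cs, s$ss)$mean_pause, 0.020)
})

test_that("waveform metrics count spikelets scale-invariantly", {
  w <- synthetic_cs_waveform(spikelet_latencies = c(0.0012, 0.0024))
  m <- cs_waveform_metrics(w)
  expect_equal(m$n_spikelets, 2)
  expect_equal(m$duration, 0.0024, tolerance = 1e-4)

  m1 <- cs_waveform_metrics(synthetic_cs_waveform(spikelet_latencies = numeric(0)))
  expect_equal(m1$n_spikelets, 0)
  expect_equal(m1$duration, 0)

  m2 <- cs_waveform_metrics(2 * w)
  expect_equal(m2$n_spikelets, m$n_spikelets)
  expect_equal(m2$duration, m$duration)

  expect_error(cs_waveform_metrics(rep(1, 100)), "flat")
})
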