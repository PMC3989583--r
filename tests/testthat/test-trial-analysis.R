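alternating_table <- function(n = 10) {
  data.frame(onset = (0:(n - 1)) * 1.096,
             direction = rep(c("ipsiversive", "contraversive"), length.out = n),
             cs_in_window = FALSE)
}

test_that("'on'-direction selection matches the training condition", {
  tab <- alternating_table(10)
  inc <- select_on_direction(tab, "increase")
  dec <- select_on_direction(tab, "decrease")
  expect_true(all(inc$direction == "ipsiversive"))
  expect_true(all(dec$direction == "contraversive"))
  expect_equal(nrow(inc), 5)
  expect_equal(sort(c(inc$onset, dec$onset)), tab$onset)  # partition
  expect_error(select_on_direction(tab, "sideways"))
})

test_that("CF window flagging is half-open [75, 250) ms", {
  tab <- data.frame(onset = c(0, 10))
  expect_true(flag_cs_in_window(tab, c(0.075))$cs_in_window[1])
  expect_false(flag_cs_in_window(tab, c(0.250))$cs_in_window[1])
  expect_false(flag_cs_in_window(tab, c(0.0749))$cs_in_window[1])
  expect_true(flag_cs_in_window(tab, c(10.2))$cs_in_window[2])
})

test_that("pair classification matches the enumerated example", {
  tab <- data.frame(onset = 1:6, direction = "ipsiversive",
                    cs_in_window = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  p <- sort_pairs(classify_pairs(tab))
  expect_equal(p$class[p$first == 1], "cf_nocf")
  expect_equal(p$class[p$first == 5], "cf_nocf")
  expect_equal(p$class[p$first == 2], "nocf_nocf")
  expect_equal(p$class[p$first == 3], "nocf_cf")
  expect_equal(p$class[p$first == 4], "cf_cf")
  expect_equal(nrow(p), 5)

  tab$cs_in_window <- FALSE
  expect_true(all(classify_pairs(tab)$class == "nocf_nocf"))
})

test_that("pair classification equals brute-force enumeration", {
  set.seed(123)
  for (i in 1:60) {
    tab <- random_trial_table(30, with_block = i %% 3 == 0)
    expect_identical(sort_pairs(classify_pairs(tab)),
                     sort_pairs(brute_force_pairs(tab)))
  }
})

test_that("pair classes partition the valid consecutive pairs", {
  set.seed(5)
  tab <- random_trial_table(50)
  tab$valid <- TRUE
  p <- classify_pairs(tab)
  n_per_dir <- table(tab$direction)
  expect_equal(nrow(p), sum(pmax(n_per_dir - 1, 0)))
  # invalid trials drop their pairs
  tab$valid[3] <- FALSE
  p2 <- classify_pairs(tab)
  expect_false(any(p2$first == 3 | p2$second == 3))
})

test_that("pair difference traces reproduce constant offsets", {
  n_trials <- 8
  resp <- matrix(5, n_trials, 50)
  tab <- data.frame(onset = seq_len(n_trials), direction = "ipsiversive",
                    cs_in_window = rep(c(TRUE, FALSE), 4))
  pairs <- classify_pairs(tab)

  same <- pair_difference_trace(pairs, resp, "cf_nocf")
  expect_true(all(same$trace == 0))

  # second trial of every pair 8 sp/s lower
  resp2 <- resp
  resp2[seq(2, 8, by = 2), ] <- resp2[seq(2, 8, by = 2), ] - 8
  dn <- pair_difference_trace(pairs, resp2, "cf_nocf")
  expect_true(all(dn$trace == -8))

  tab0 <- tab; tab0$cs_in_window <- FALSE
  expect_warning(
    z <- pair_difference_trace(classify_pairs(tab0), resp, "cf_nocf"),
    "no pairs")
  expect_equal(z$n_pairs, 0)
})

test_that("grand average weights cells equally", {
  one <- grand_average(list(c(1, 2, 3)))
  expect_equal(one$mean, c(1, 2, 3))
  sym <- grand_average(list(c(2, 2), c(-2, -2)))
  expect_equal(sym$mean, c(0, 0))
  # a cell with many pairs must not dominate: traces enter pre-averaged
  g <- grand_average(list(rep(10, 4), rep(-2, 4)))
  expect_equal(g$mean, rep(4, 4))
  expect_equal(g$n_cells, 2)
})

test_that("bootstrap band is degenerate for all-zero pools and checks counts", {
  pools <- list(matrix(0, 20, 10), matrix(0, 15, 10))
  b <- bootstrap_null(pools, c(5, 4), n_reps = 100, smooth = 0, sample_rate = 500)
  expect_equal(b$lower, rep(0, 10))
  expect_equal(b$upper, rep(0, 10))
  expect_error(bootstrap_null(pools, c(30, 4), n_reps = 10, replace = FALSE),
               "exceeds pool size")
})

test_that("session slope is the OLS slope of response vs trial number", {
  k <- 1:35
  exact <- session_slope(10 - 0.2 * k)
  expect_equal(exact$slope, -0.2, tolerance = 1e-12)
  expect_equal(exact$intercept, 10, tolerance = 1e-10)
  expect_equal(session_slope(rep(4, 10))$slope, 0)
  expect_error(session_slope(c(1, 2)), "3 valid trials")

  set.seed(31)
  miss <- 0
  for (i in 1:50) {
    y <- -0.2 * k + stats::rnorm(35)
    est <- session_slope(y)
    se <- sqrt(1 / sum((k - mean(k))^2))
    if (abs(est$slope + 0.2) > 3 * se) miss <- miss + 1
  }
  expect_lte(miss, 3)  # ~0.3% expected per draw
})

test_that("group test of slopes against zero behaves at the extremes", {
  z <- slopes_group_test(rep(0, 5))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
  neg <- slopes_group_test(c(-1.1, -0.9, -1.05, -0.95))
  expect_lt(neg$t, 0)
  expect_lt(neg$p, 0.01)
})

test_that("full cell analysis recovers implanted plasticity on a small cohort", {
  # |delta| * p * n_trials kept well below the cell's firing range so the
  # accumulating implant stays clear of the rate floor
  sessions <- quick_cells(n_cells = 8, n_trials = 120, seed = 50,
                          plasticity_delta = -8, cs_prob_in_window = 0.07)
  res <- trial_by_trial_analysis(sessions, n_reps = 200)
  cf <- mean(res$classes$cf_nocf$grand$mean)
  expect_lt(cf, -4)
  expect_gt(cf, -12)
  # flags recovered from spikes equal ground truth for every cell
  for (s in sessions) {
    fl <- flag_cs_in_window(s$trials, s$cs)$cs_in_window
    expect_identical(fl, s$ground_truth$trials$cs_in_window)
  }
})
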