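test_that("linear rescaling maps thresholds onto the pool parameter ranges", {
  b <- pool_bounds(p_max = 100, tr_min = 0.03, tr_max = 0.24,
                   thr_min = 0.015, thr_max = 0.14)
  tw <- rescale_twitch_params(c(2, 17, 32), b)
  expect_equal(tw$p, c(1, 50.5, 100))
  expect_equal(tw$tr, c(0.03, 0.135, 0.24))
  expect_equal(tw$thr, c(0.015, 0.0775, 0.14))
  # monotone in threshold
  expect_true(all(diff(tw$p) > 0) && all(diff(tw$tr) > 0))
  # all-equal thresholds (and single units) collapse to the minima
  flat <- rescale_twitch_params(c(10, 10, 10), b)
  expect_true(all(flat$p == 1) && all(flat$tr == 0.03))
  expect_equal(rescale_twitch_params(25, b)$thr, 0.015)
})

test_that("the twitch rises to P at Tr and halves one Thr later", {
  expect_equal(twitch_value(0, 10, 0.05, 0.03), 0)
  expect_equal(twitch_value(0.05, 10, 0.05, 0.03), 10)
  expect_equal(twitch_value(0.08, 10, 0.05, 0.03), 5)
  expect_equal(twitch_value(0.11, 10, 0.05, 0.03), 2.5)
  w <- twitch_waveform(10, 0.05, 0.03, fs = 2000)
  expect_equal(max(w), 10, tolerance = 1e-4)
  expect_equal((which.max(w) - 1) / 2000, 0.05, tolerance = 1 / 2000)
  expect_lt(w[length(w)], 10 * 2e-4)
  expect_error(twitch_waveform(-1, 0.05, 0.03, 100), "positive")
})

test_that("the rate-dependent gain is continuous at the knee", {
  expect_equal(spike_gain(0.04, 0.1), 1)        # x = 0.4, knee
  expect_equal(spike_gain(0.02, 0.1), 1)        # x = 0.2, below knee
  x <- 1
  s <- function(z) 1 - exp(-2 * z^3)
  expected <- (s(x) / x) / (s(0.4) / 0.4)
  expect_equal(spike_gain(0.05, 0.05), expected, tolerance = 1e-12)
  expect_equal(expected, 2.8788, tolerance = 1e-4)  # frozen regression value
  # continuity just above the knee
  expect_equal(spike_gain(0.0401, 0.1), 1, tolerance = 0.01)
})

test_that("the MUDrive signal equals the brute-force spike loop", {
  duration <- 15
  firings <- withr::with_seed(21, random_pool_firings(4, duration))
  p <- c(2, 5, 9, 14)
  tr <- c(0.04, 0.07, 0.1, 0.13)
  thr <- c(0.02, 0.05, 0.09, 0.12)
  got <- mudrive_signal(firings, p, tr, thr, duration, fs = 100)
  want <- oracle_twitch_sum(firings, p, tr, thr, duration, fs = 100)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)

  # one unit, one spike: the twitch itself
  w <- twitch_waveform(5, 0.06, 0.04, fs = 100)
  one <- mudrive_signal(list(0.5), 5, 0.06, 0.04, duration = 3, fs = 100)
  i0 <- round(0.5 * 100) + 1
  expect_equal(one[i0:(i0 + length(w) - 1)], w, tolerance = 1e-9)

  # linearity across units
  both <- mudrive_signal(firings[1:2], p[1:2], tr[1:2], thr[1:2], duration, 100)
  u1 <- mudrive_signal(firings[1], p[1], tr[1], thr[1], duration, 100)
  u2 <- mudrive_signal(firings[2], p[2], tr[2], thr[2], duration, 100)
  expect_equal(both, u1 + u2, tolerance = 1e-10)
})

test_that("MUDrive predictions are invariant to uniform peak-force scaling", {
  rec <- recovery_prep(33)
  b1 <- recovery_truth()
  b2 <- pool_bounds(p_min = 10 * b1$p_min, p_max = 10 * b1$p_max,
                    tr_min = b1$tr_min, tr_max = b1$tr_max,
                    thr_min = b1$thr_min, thr_max = b1$thr_max)
  m1 <- fit_mudrive(rec$units, b1, rec$prep$torque_ref, rec$prep$duration,
                    config = rec$prep$config)
  m2 <- fit_mudrive(rec$units, b2, rec$prep$torque_ref, rec$prep$duration,
                    config = rec$prep$config)
  expect_equal(m1$train_rmse, m2$train_rmse, tolerance = 1e-9)
  expect_equal(m1$coefficients, 10 * m2$coefficients, tolerance = 1e-9)
})

test_that("a torque built from the smoothed MUDrive signal is fit exactly", {
  rec <- recovery_prep(34)
  prep <- rec$prep
  tw <- rescale_twitch_params(rec$units$rt, recovery_truth())
  feat <- mudecode:::mudrive_feature(rec$units$firings, tw, prep$duration,
                                     100, prep$config)
  fake_torque <- dplyr::mutate(feat, value = 2 * value + 1)
  m <- fit_mudrive(rec$units, recovery_truth(), fake_torque, prep$duration,
                   config = prep$config)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-8)
  expect_equal(m$intercept, 1, tolerance = 1e-6)
  expect_lt(m$train_rmse, 1e-8)
})
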