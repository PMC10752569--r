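# brute-force windowed statistic sharing the half-open [c - w/2, c + w/2)
# convention: sample k sits at (k - 1) / fs
oracle_windowed <- function(x, fs, window, step, fun) {
  duration <- length(x) / fs
  centers <- seq(window / 2, duration - window / 2 + 1e-9, by = step)
  t <- (seq_along(x) - 1) / fs
  vapply(centers, function(cc) {
    fun(x[t >= cc - window / 2 - 1e-9 & t < cc + window / 2 - 1e-9])
  }, numeric(1))
}

test_that("torque preprocessing removes offset and attenuates fast content", {
  fs <- 100
  const <- preprocess_torque(rep(7.3, 500), fs = fs)
  expect_feature_series(const)
  expect_true(all(abs(const$value) < 1e-8))

  t <- seq(0, 9.99, by = 1 / fs)
  wig <- preprocess_torque(4 + sin(2 * pi * 50 * t), fs = fs)
  expect_lt(max(abs(wig$value)), 0.01)

  # a slow ramp passes through with unit DC gain
  ramp <- preprocess_torque(seq(0, 10, length.out = 1000) + 2, fs = fs)
  mid <- ramp$value[ramp$time > 3 & ramp$time < 7]
  slope <- coef(lm(mid ~ ramp$time[ramp$time > 3 & ramp$time < 7]))[2]
  expect_equal(unname(slope), 1, tolerance = 0.02)

  expect_error(preprocess_torque(rep(1, 50), fs = fs), "2 s")
})

test_that("the EMG band-pass keeps the passband and rejects band edges", {
  fs <- 2222
  t <- seq(0, 4, by = 1 / fs)
  dc <- bandpass_emg(rep(3, length(t)), fs = fs)
  expect_true(all(abs(dc[t > 0.5 & t < 3.5]) < 1e-6))
  in_band <- bandpass_emg(sin(2 * pi * 100 * t), fs = fs)
  mid <- in_band[t > 1 & t < 3]
  expect_lt(abs(max(abs(mid)) - 1), 0.05)
  low <- bandpass_emg(sin(2 * pi * 5 * t), fs = fs)
  expect_lt(max(abs(low[t > 1 & t < 3])), 0.1)
})

test_that("moving RMS matches closed forms and a brute-force loop", {
  fs <- 1000
  const <- moving_rms(rep(-2, 3000), fs = fs)
  expect_true(all(abs(const$value - 2) < 1e-12))

  t <- seq(0, 3, by = 1 / fs)
  sine <- moving_rms(3 * sin(2 * pi * 40 * t), fs = fs)
  interior <- sine$value[sine$time > 0.5 & sine$time < 2.5]
  expect_true(all(abs(interior - 3 / sqrt(2)) / (3 / sqrt(2)) < 0.01))

  x <- withr::with_seed(4, rnorm(2500))
  got <- moving_rms(x, fs = fs)
  want <- oracle_windowed(x, fs, 0.5, 0.1, function(v) sqrt(mean(v^2)))
  expect_equal(got$value, want, tolerance = 1e-12)
})

test_that("firing-rate series counts discharges per centered window", {
  s <- firing_rate_series(c(1.01, 1.05, 1.1, 1.15, 1.2), duration = 3)
  expect_equal(s$value[s$time == 1.05], 10)  # 5 spikes / 0.5 s
  empty <- firing_rate_series(numeric(0), duration = 3)
  expect_true(all(empty$value == 0))
  # long Poisson train: time-averaged rate near the generating rate
  lambda <- 12
  f <- withr::with_seed(9, cumsum(rexp(round(lambda * 40), lambda)))
  f <- f[f < 30]
  s <- firing_rate_series(f, duration = 30)
  se <- sqrt(lambda / 30)
  expect_lt(abs(mean(s$value) - lambda), 2 * se)
  expect_error(firing_rate_series(c(2, 1), duration = 3), "sorted")
})

test_that("the Kalman smoother is a variance-reducing, scale-equivariant filter", {
  grid <- seq(0.25, 20, 0.1)
  const <- kalman_smooth(tibble::tibble(time = grid, value = rep(5, length(grid))))
  expect_true(all(const$value == 5))

  noisy <- tibble::tibble(time = grid, value = withr::with_seed(2, rnorm(length(grid))))
  sm <- kalman_smooth(noisy)
  expect_lt(var(sm$value), var(noisy$value))

  # measurement variance -> 0 reproduces the input
  id <- kalman_smooth(noisy, process_var = 1, measurement_var = 1e-14)
  expect_equal(id$value, noisy$value, tolerance = 1e-6)

  # default variances scale with the series, so smoothing commutes with gain
  expect_equal(kalman_smooth(dplyr::mutate(noisy, value = value * 7))$value,
               7 * sm$value, tolerance = 1e-9)
})

test_that("cross-correlation alignment recovers constructed lags", {
  grid <- seq(0.25, 30, 0.1)
  ref <- tibble::tibble(time = grid, value = pmax(0, sin(grid / 3)))
  delayed <- tibble::tibble(time = grid, value = pmax(0, sin((grid - 0.3) / 3)))
  al <- align_by_xcorr(delayed, ref)
  expect_equal(al$lag, 0.3)
  expect_equal(nrow(al$feature), nrow(al$reference))

  expect_equal(align_by_xcorr(ref, ref)$lag, 0)

  noisy <- tibble::tibble(
    time = grid,
    value = 3 * pmax(0, sin((grid - 0.5) / 3)) +
      withr::with_seed(6, rnorm(length(grid), sd = 0.3))
  )
  expect_equal(align_by_xcorr(noisy, ref)$lag, 0.5)

  # constant feature: degenerate, lag defined as 0
  flat <- tibble::tibble(time = grid, value = rep(1, length(grid)))
  expect_equal(align_by_xcorr(flat, ref)$lag, 0)
})

test_that("MVC normalization rescales to percent of the reference", {
  s <- tibble::tibble(time = 1:3 / 10, value = c(0, 0.4, 0.8))
  out <- normalize_to_mvc(s, mvc_rms = 0.8)
  expect_equal(out$value, c(0, 50, 100))
  expect_error(normalize_to_mvc(s, 0), "positive")
})

test_that("the MVC reference is the maximum sliding-window RMS", {
  fs <- 1000
  expect_equal(compute_mvc(rep(-3, 2000), fs = fs), 3)
  quiet <- rep(0.01, 5000)
  burst <- quiet
  burst[2000:2600] <- 2
  expect_gt(compute_mvc(burst, fs = fs), 1.5)
  x <- withr::with_seed(12, rnorm(4000))
  w <- round(0.5 * fs)
  want <- max(vapply(seq_len(length(x) - w + 1), function(i) {
    sqrt(mean(x[i:(i + w - 1)]^2))
  }, numeric(1)))
  expect_equal(compute_mvc(x, fs = fs), want, tolerance = 1e-12)
})

test_that("windowed operators ignore samples strictly outside every window", {
  # grid covers [w/2, duration - w/2]; appending firings after the last
  # window leaves the series over the original grid unchanged
  f <- c(1.0, 1.2, 1.4)
  a <- firing_rate_series(f, duration = 3)
  b <- firing_rate_series(c(f, 2.9), duration = 3)
  keep <- a$time < 2.6
  expect_equal(a$value[keep], b$value[keep])
})
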