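test_that("recruitment thresholds follow the exponential ladder", {
  pool <- generate_pool(pool_config(n_units = 3, rt_min = 2,
                                    recruitment_range = 16))
  expect_equal(pool$rt_true, c(2, 8, 32))
  # single-unit pool sits at rt_min regardless of the range
  one <- generate_pool(pool_config(n_units = 1, rt_min = 3,
                                   recruitment_range = 30))
  expect_equal(one$rt_true, 3)
})

test_that("ground-truth twitch parameters follow the size principle", {
  cfg <- pool_config(n_units = 5)
  pool <- generate_pool(cfg)
  tb <- cfg$true_bounds
  expect_equal(pool$p_true[1], tb$p_min)
  expect_equal(pool$tr_true[1], tb$tr_min)
  expect_equal(pool$thr_true[1], tb$thr_min)
  expect_equal(pool$p_true[5], tb$p_max)
  expect_true(all(diff(pool$p_true) > 0))
  expect_true(all(diff(pool$tr_true) > 0))
  expect_true(all(diff(pool$thr_true) > 0))
  # MUAP templates: zero-mean, biphasic, amplitude nondecreasing with RT
  p2p <- vapply(pool$muap, function(w) max(w) - min(w), numeric(1))
  expect_true(all(diff(p2p) >= 0))
  expect_true(all(abs(vapply(pool$muap, mean, numeric(1))) < 1e-12))
})

test_that("units fire only above threshold, in recruitment order", {
  cfg <- pool_config(n_units = 6, recruitment_range = 8, rt_min = 2)
  prof <- trapezoid_profile(20, n_trapezoids = 1)
  pool <- withr::with_seed(3, simulate_spike_trains(generate_pool(cfg), prof, cfg))
  first_fire <- vapply(pool$firings, min, numeric(1))
  expect_true(all(diff(first_fire) > 0))
  exc <- approxfun(prof$time, prof$excitation)
  for (i in seq_len(nrow(pool))) {
    expect_true(all(exc(pool$firings[[i]]) > pool$rt_true[i]))
  }
})

test_that("zero excitation produces empty spike trains", {
  cfg <- pool_config(n_units = 3)
  prof <- tibble::tibble(time = seq(0, 10, 0.001), excitation = 0)
  pool <- simulate_spike_trains(generate_pool(cfg), prof, cfg)
  expect_true(all(lengths(pool$firings) == 0))
})

test_that("jitter-free trains at constant drive have exactly regular ISIs", {
  cfg <- pool_config(n_units = 1, rt_min = 5, isi_cv = 0)
  prof <- tibble::tibble(time = seq(0, 10, 0.001), excitation = 15)
  pool <- withr::with_seed(1, simulate_spike_trains(generate_pool(cfg), prof, cfg))
  isis <- diff(pool$firings[[1]])
  expected <- 1 / min(cfg$peak_rate, cfg$min_rate + cfg$rate_gain * (15 - 5))
  expect_true(all(abs(isis - expected) < 1e-9))
})

test_that("empirical hold-period rate matches the rate-coding model", {
  cfg <- pool_config(n_units = 4, recruitment_range = 8, rt_min = 2)
  prof <- trapezoid_profile(20, n_trapezoids = 1)
  pool <- withr::with_seed(11, simulate_spike_trains(generate_pool(cfg), prof, cfg))
  traps <- attr(prof, "trapezoids")
  hold <- c(traps$start + 2, traps$end - 2)  # the 12-s plateau
  f <- pool$firings[[1]]
  n_hold <- sum(f >= hold[1] & f < hold[2])
  model_rate <- min(cfg$peak_rate,
                    cfg$min_rate + cfg$rate_gain * (20 - pool$rt_true[1]))
  expect_lt(abs(n_hold / 12 - model_rate) / model_rate, 0.05)
})

test_that("EMG synthesis is an exact MUAP superposition", {
  cfg <- pool_config(n_units = 1, emg_snr_db = Inf)
  pool <- generate_pool(cfg)
  pool$firings <- list(1.0)
  emg <- synthesize_emg(pool, cfg, duration = 2)
  w <- pool$muap[[1]]
  i0 <- round(1.0 * cfg$emg_fs) + 1 - length(w) %/% 2
  expect_equal(emg[i0:(i0 + length(w) - 1)], w)
  expect_true(all(emg[-(i0:(i0 + length(w) - 1))] == 0))

  # opposite-polarity simultaneous firings cancel exactly
  pool2 <- dplyr::bind_rows(pool, pool)
  pool2$muap[[2]] <- -pool2$muap[[1]]
  pool2$firings <- list(1.0, 1.0)
  expect_true(all(synthesize_emg(pool2, cfg, duration = 2) == 0))
})

test_that("additive EMG noise hits the configured SNR", {
  cfg <- small_clean_config(emg_snr_db = 20)
  b <- small_bundle()
  pool <- b$units
  pool$firings <- pool$firings_true
  clean <- synthesize_emg(pool, cfg, duration = b$duration, snr_db = Inf)
  noisy <- withr::with_seed(5, synthesize_emg(pool, cfg, duration = b$duration,
                                              snr_db = 20))
  noise <- noisy - clean
  snr <- 20 * log10(sqrt(mean(clean[clean != 0]^2)) / sd(noise))
  expect_lt(abs(snr - 20), 1)
})

test_that("summed EMG shows amplitude cancellation", {
  b <- small_bundle()
  cfg <- small_clean_config()
  pool <- b$units
  pool$firings <- pool$firings_true
  total <- synthesize_emg(pool, cfg, duration = b$duration, snr_db = Inf)
  per_unit_rms <- vapply(seq_len(nrow(pool)), function(i) {
    sqrt(mean(synthesize_emg(pool[i, ], cfg, duration = b$duration,
                             snr_db = Inf)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(total^2)), sum(per_unit_rms))
})

test_that("torque synthesis matches a spike-by-spike oracle and is linear", {
  cfg <- pool_config(n_units = 3, torque_noise_sd = 0)
  pool <- generate_pool(cfg)
  pool$firings <- withr::with_seed(8, random_pool_firings(3, 20))
  tq <- synthesize_torque(pool, cfg, duration = 20)
  oracle <- oracle_twitch_sum(pool$firings, pool$p_true, pool$tr_true,
                              pool$thr_true, 20, cfg$torque_fs)
  expect_lt(max(abs(tq - oracle)) / max(abs(oracle)), 1e-9)
  # linearity: adding a unit adds exactly its contribution
  tq12 <- synthesize_torque(pool[1:2, ], cfg, duration = 20)
  tq3 <- synthesize_torque(pool[3, ], cfg, duration = 20)
  expect_equal(tq, tq12 + tq3, tolerance = 1e-12)
  # no firings: zero-mean noise only
  empty <- pool[1, ]
  empty$firings <- list(numeric(0))
  expect_true(all(synthesize_torque(empty, cfg, duration = 5) == 0))
})

test_that("identical configuration and seed give bit-identical bundles", {
  cfg <- pool_config(n_units = 8, n_decomposed = 5)
  b1 <- simulate_trial_bundle(cfg, target_mvc = 20, seed = 17)
  b2 <- simulate_trial_bundle(cfg, target_mvc = 20, seed = 17)
  expect_identical(b1, b2)
  b3 <- simulate_trial_bundle(cfg, target_mvc = 20, seed = 18)
  expect_false(identical(b1$emg, b3$emg))
})

test_that("the decomposed subset is active and biased toward large units", {
  b <- simulate_trial_bundle(pool_config(), target_mvc = 20, seed = 19)
  expect_equal(sum(b$units$decomposed), 25)
  dec <- b$units[b$units$decomposed, ]
  expect_true(all(lengths(dec$firings_true) >= 20))
})
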