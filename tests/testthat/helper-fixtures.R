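# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small fully observed clean pool: fast bundle for decoder/validation tests
small_clean_config <- function(...) {
  pool_config(n_units = 12, n_decomposed = NULL, recruitment_range = 8,
              miss_rate = 0, false_rate = 0, ...)
}

small_bundle <- function() {
  cached("small_bundle", function() {
    simulate_trial_bundle(small_clean_config(), target_mvc = 20,
                          n_trapezoids = 2, seed = 7)
  })
}

# identifiable construction for twitch-parameter recovery: fully recruited
# pool, sub-knee firing rates (fusion gain inert), known thresholds and
# near-identity Kalman smoothing
recovery_truth <- function() {
  b <- pool_bounds()
  b$tr_min <- 0.05
  b
}

recovery_config <- function() {
  pool_config(n_units = 12, n_decomposed = NULL, recruitment_range = 8,
              miss_rate = 0, false_rate = 0, true_bounds = recovery_truth(),
              min_rate = 6, rate_gain = 0.1, isi_cv = 0.1,
              torque_noise_sd = 0.1, emg_snr_db = 30, muap_amp_scaling = 0.2)
}

recovery_decoder_config <- function() {
  decoder_config(max_units = 12, kalman_process_var = 1,
                 kalman_measurement_var = 1e-12)
}

# training-fold preparation + retained units with true thresholds
recovery_prep <- function(seed) {
  b <- simulate_trial_bundle(recovery_config(), target_mvc = 20,
                             n_trapezoids = 2, seed = seed)
  folds <- split_bundle(b)
  prep <- mudecode:::prepare_fold(folds[[1]], recovery_decoder_config())
  units <- mudecode:::mudrive_units(prep)
  units$rt <- b$units$rt_true[match(units$id, b$units$id)]
  list(bundle = b, prep = prep, units = units)
}

# default 8-virtual-subject cohort under the study conditions (GA scaled to
# population 15 / 20 generations inside cohort_config); shared between the
# headline-ordering, level-effect and refinement checks
default_cohort <- function() {
  cached("default_cohort", function() run_cohort(cohort_config(), seed = 1))
}

# same cohort with the midpoint (no-optimization) MUDrive baseline
midpoint_cohort <- function() {
  cached("midpoint_cohort", function() {
    run_cohort(cohort_config(), seed = 1, methods = c("aEMG", "MUDrive"),
               mudrive_optimize = FALSE)
  })
}

# brute-force oracle: place the sampled twitch kernel spike by spike
oracle_twitch_sum <- function(firings, p, tr, thr, duration, fs) {
  n <- floor(duration * fs) + 1L
  out <- numeric(n)
  for (u in seq_along(firings)) {
    f <- firings[[u]]
    if (length(f) == 0) next
    w <- twitch_waveform(p[u], tr[u], thr[u], fs)
    g <- if (length(f) == 1) 1 else c(1, spike_gain(tr[u], diff(f)))
    for (k in seq_along(f)) {
      i0 <- round(f[k] * fs) + 1L
      idx <- i0:(i0 + length(w) - 1L)
      keep <- idx >= 1L & idx <= n
      out[idx[keep]] <- out[idx[keep]] + g[k] * w[keep]
    }
  }
  out
}

random_pool_firings <- function(n_units, duration, rate = 12) {
  lapply(seq_len(n_units), function(u) {
    sort(runif(stats::rpois(1, rate * duration), 0, duration))
  })
}

expect_feature_series <- function(x) {
  expect_s3_class(x, "tbl_df")
  expect_named(x, c("time", "value"))
  expect_true(all(diff(x$time) > 0))
}
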