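#' Configuration of a synthetic motor-unit pool
#'
#' Describes the statistical structure of a simulated motor-unit pool and
#' trial: recruitment thresholds on an exponential ladder (mimicking the
#' skew of real recruitment distributions toward low thresholds), linear
#' rate coding with saturation and ISI jitter, biphasic MUAP templates with
#' amplitude increasing with recruitment threshold, EMG formed by MUAP
#' superposition (so amplitude cancellation occurs) plus white noise, and
#' torque formed by twitch superposition with ground-truth twitch
#' parameters plus white noise.
#'
#' @param n_units Number of motor units in the physiological pool (all of
#'   them generate EMG and torque).
#' @param n_decomposed Number of units exposed to the decoders as the
#'   "decomposed" set: surface decomposition recovers only a minority of
#'   the pool, biased toward large units, so a size-biased subset of the
#'   active units is marked as decomposed. `NULL` (or a value at least
#'   `n_units`) exposes the whole pool.
#' @param rt_min Recruitment threshold of the smallest unit (%MVC).
#' @param recruitment_range Ratio of the largest to the smallest
#'   recruitment threshold (dimensionless).
#' @param min_rate Firing rate at recruitment (Hz).
#' @param peak_rate Firing-rate saturation (Hz).
#' @param rate_gain Rate increase per %MVC of excitation above the
#'   recruitment threshold (Hz per %MVC).
#' @param isi_cv Coefficient of variation of inter-spike-interval jitter.
#' @param true_bounds Ground-truth [pool_bounds()] used to assign per-unit
#'   twitch parameters.
#' @param muap_duration MUAP template duration (s).
#' @param muap_amp_scaling Exponent linking recruitment threshold to MUAP
#'   peak-to-peak amplitude (amplitude proportional to RT^exponent).
#' @param muap_amp_base Amplitude scale (volts) of a unit with RT = 1 %MVC.
#' @param emg_fs EMG sampling rate (Hz).
#' @param torque_fs Torque sampling rate (Hz).
#' @param miss_rate Fraction of true discharges missed by the emulated
#'   decomposition (applied to the observed spike trains of decomposed
#'   units only; the true trains still generate EMG and torque).
#' @param false_rate Expected number of spurious discharges inserted by
#'   the emulated decomposition, as a fraction of the unit's true
#'   discharge count.
#' @param emg_snr_db EMG signal-to-noise ratio (dB) relative to the RMS of
#'   the clean signal over active segments; `Inf` disables noise.
#' @param torque_noise_sd SD of additive torque noise (torque units).
#' @param torque_scale Global factor mapping summed twitch force (arbitrary
#'   units) to Nm.
#'
#' @return A list of class `pool_config`.
#' @examples
#' pool_config(n_units = 10)
#' @export
pool_config <- function(n_units = 100, n_decomposed = 25, rt_min = 2,
                        recruitment_range = 30,
                        min_rate = 8, peak_rate = 35, rate_gain = 0.7,
                        isi_cv = 0.2, miss_rate = 0.1, false_rate = 0.1,
                        true_bounds = pool_bounds(),
                        muap_duration = 0.015, muap_amp_scaling = 1,
                        muap_amp_base = 5e-5, emg_fs = 2222, torque_fs = 100,
                        emg_snr_db = 20, torque_noise_sd = 0.5,
                        torque_scale = 1) {
  if (n_units < 1) abort("`n_units` must be at least 1")
  if (!(min_rate > 0 && peak_rate > min_rate)) {
    abort("need 0 < min_rate < peak_rate")
  }
  if (isi_cv < 0) abort("`isi_cv` must be nonnegative")
  if (emg_fs <= 0 || torque_fs <= 0) abort("sampling rates must be positive")
  structure(list(
    n_units = n_units, n_decomposed = n_decomposed, rt_min = rt_min,
    recruitment_range = recruitment_range,
    min_rate = min_rate, peak_rate = peak_rate, rate_gain = rate_gain,
    isi_cv = isi_cv, miss_rate = miss_rate, false_rate = false_rate,
    true_bounds = true_bounds,
    muap_duration = muap_duration, muap_amp_scaling = muap_amp_scaling,
    muap_amp_base = muap_amp_base, emg_fs = emg_fs, torque_fs = torque_fs,
    emg_snr_db = emg_snr_db, torque_noise_sd = torque_noise_sd,
    torque_scale = torque_scale
  ), class = "pool_config")
}

#' Generate a recruitment-ordered motor-unit pool
#'
#' Recruitment thresholds follow an exponential ladder
#' `RT_i = rt_min * recruitment_range^((i - 1) / (n - 1))`, spanning
#' `[rt_min, rt_min * recruitment_range]` %MVC, so most units sit at low
#' thresholds. Ground-truth twitch parameters are assigned by the same
#' linear rescaling rule the decoder uses ([rescale_twitch_params()])
#' applied to the configured true bounds, so higher-threshold units get
#' larger peak forces, longer rise times and longer half-relaxation times.
#' MUAP templates are zero-mean biphasic waveforms (first derivative of a
#' Gaussian) whose peak-to-peak amplitude grows monotonically with
#' recruitment threshold.
#'
#' @param config A [pool_config()].
#' @return A tibble with one row per unit: `id`, `rt_true` (%MVC),
#'   ground-truth twitch parameters `p_true`, `tr_true`, `thr_true`, and a
#'   list-column `muap` of template waveforms sampled at `emg_fs`.
#' @examples
#' generate_pool(pool_config(n_units = 5))
#' @export
generate_pool <- function(config) {
  n <- config$n_units
  if (n == 1) {
    rt <- config$rt_min
  } else {
    rt <- config$rt_min * config$recruitment_range^((seq_len(n) - 1) / (n - 1))
  }
  tw <- rescale_twitch_params(rt, config$true_bounds)
  base <- muap_template(config$muap_duration, config$emg_fs)
  amp <- config$muap_amp_base * rt^config$muap_amp_scaling
  muaps <- lapply(amp, function(a) a * base)
  tibble::tibble(
    id = seq_len(n),
    rt_true = rt,
    p_true = tw$p,
    tr_true = tw$tr,
    thr_true = tw$thr,
    muap = muaps
  )
}

# biphasic zero-mean template: first derivative of a Gaussian, unit
# peak-to-peak amplitude, length = duration * fs samples
muap_template <- function(duration, fs) {
  n <- max(round(duration * fs), 3)
  t <- seq(-duration / 2, duration / 2, length.out = n)
  sigma <- duration / 8
  w <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))
  w <- w - mean(w)
  w / (max(w) - min(w))
}

#' Simulate spike trains for a pool under an excitation profile
#'
#' Each unit fires only while the excitation exceeds its recruitment
#' threshold. The instantaneous rate is
#' `min_rate + rate_gain * (excitation - RT)`, capped at `peak_rate`;
#' successive inter-spike intervals are Gaussian-perturbed with coefficient
#' of variation `isi_cv` and truncated at a 2-ms minimum. Reproducible for
#' a given RNG state.
#'
#' @param pool Unit tibble from [generate_pool()].
#' @param profile Excitation profile from [trapezoid_profile()].
#' @param config The [pool_config()].
#' @return The pool tibble with an added list-column `firings` (discharge
#'   times in s).
#' @examples
#' cfg <- pool_config(n_units = 3)
#' pool <- generate_pool(cfg)
#' prof <- trapezoid_profile(20, n_trapezoids = 1)
#' simulate_spike_trains(pool, prof, cfg)
#' @export
simulate_spike_trains <- function(pool, profile, config) {
  exc_t <- profile$time
  exc_v <- profile$excitation
  exc_fun <- approxfun(exc_t, exc_v, rule = 2)
  t_end <- max(exc_t)
  pool$firings <- lapply(pool$rt_true, function(rt) {
    above <- exc_v > rt
    if (!any(above)) return(numeric(0))
    spikes <- numeric(0)
    # start at the first recruitment crossing
    t <- exc_t[which(above)[1]]
    repeat {
      if (t > t_end) break
      e <- exc_fun(t)
      if (e > rt) {
        spikes <- c(spikes, t)
        rate <- min(config$peak_rate, config$min_rate +
                      config$rate_gain * (e - rt))
        isi <- (1 / rate) * (1 + config$isi_cv * rnorm(1))
        t <- t + max(isi, 0.002)
      } else {
        # jump forward to the next recruitment crossing
        nxt <- which(above & exc_t > t)
        if (length(nxt) == 0) break
        t <- exc_t[nxt[1]]
      }
    }
    spikes
  })
  pool
}

#' Synthesize surface EMG by MUAP superposition
#'
#' Sums every unit's MUAP template shifted to each of its discharge times
#' (templates centered at the firing instant), then adds white Gaussian
#' noise at `emg_snr_db` dB relative to the RMS of the clean signal over
#' active samples. Because overlapping MUAPs of mixed polarity partially
#' cancel, the amplitude of the summed signal grows sublinearly with
#' drive — the MUAP-cancellation phenomenon.
#'
#' @param pool Unit tibble with `firings` and `muap` columns.
#' @param config The [pool_config()].
#' @param duration Trial duration (s).
#' @param snr_db SNR override; default taken from `config`. Use `Inf` for
#'   a noiseless trace.
#' @param active Optional logical vector (length of the output) marking
#'   active samples for the SNR reference; defaults to samples where the
#'   clean signal is nonzero.
#' @return Numeric vector of EMG samples at `emg_fs`.
#' @export
synthesize_emg <- function(pool, config, duration, snr_db = NULL,
                           active = NULL) {
  fs <- config$emg_fs
  n <- floor(duration * fs) + 1L
  clean <- numeric(n)
  for (u in seq_len(nrow(pool))) {
    w <- pool$muap[[u]]
    lw <- length(w)
    off <- -(lw %/% 2)
    for (s in pool$firings[[u]]) {
      i0 <- round(s * fs) + 1L + off
      idx <- i0:(i0 + lw - 1L)
      keep <- idx >= 1L & idx <= n
      if (any(keep)) clean[idx[keep]] <- clean[idx[keep]] + w[keep]
    }
  }
  if (is.null(snr_db)) snr_db <- config$emg_snr_db
  if (is.finite(snr_db)) {
    if (is.null(active)) active <- clean != 0
    ref <- if (any(active)) sqrt(mean(clean[active]^2)) else 0
    noise_sd <- ref * 10^(-snr_db / 20)
    clean <- clean + rnorm(n, sd = noise_sd)
  }
  clean
}

#' Synthesize torque by twitch superposition
#'
#' Ground-truth torque: every unit's spike train is convolved with its
#' ground-truth twitch waveform, each spike scaled by the rate-dependent
#' gain ([spike_gain()]), contributions summed across the pool, scaled to
#' Nm and perturbed with white Gaussian noise.
#'
#' @param pool Unit tibble with `firings` and ground-truth twitch columns.
#' @param config The [pool_config()].
#' @param duration Trial duration (s).
#' @param noise_sd Noise SD override; default from `config`.
#' @return Numeric vector of torque samples at `torque_fs`.
#' @export
synthesize_torque <- function(pool, config, duration, noise_sd = NULL) {
  x <- mudrive_signal(pool$firings, pool$p_true, pool$tr_true,
                      pool$thr_true, duration = duration,
                      fs = config$torque_fs)
  x <- x * config$torque_scale
  if (is.null(noise_sd)) noise_sd <- config$torque_noise_sd
  if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
  x
}

#' Simulate a complete trial bundle
#'
#' Builds the excitation profile, generates the pool, simulates spike
#' trains, synthesizes EMG and torque, and simulates an MVC calibration
#' contraction (3 s at 100 %MVC excitation through the same pool and EMG
#' synthesis) to obtain the MVC reference RMS. All randomness is governed
#' by `seed`; identical configuration and seed give bit-identical bundles.
#'
#' @param config A [pool_config()].
#' @param target_mvc Plateau excitation (%MVC).
#' @param n_trapezoids Number of trapezoids (default 2, matching the
#'   two-fold cross-validation design).
#' @param seed Integer seed.
#' @param ramp_rate Ramp slope (%MVC/s).
#' @return A list of class `trial_bundle`: `units` (pool tibble with
#'   firings and ground truth), `emg`, `emg_fs`, `torque`, `torque_fs`,
#'   `mvc_rms`, `profile`, `duration`, `target_mvc`, `seed`.
#' @examples
#' b <- simulate_trial_bundle(pool_config(n_units = 5), target_mvc = 20, seed = 1)
#' b$mvc_rms
#' @export
simulate_trial_bundle <- function(config, target_mvc = 20, n_trapezoids = 2,
                                  seed = 1, ramp_rate = 10) {
  withr::with_seed(seed, {
    profile <- trapezoid_profile(target_mvc, n_trapezoids = n_trapezoids,
                                 ramp_rate = ramp_rate)
    duration <- max(profile$time)
    pool <- generate_pool(config)
    pool <- simulate_spike_trains(pool, profile, config)
    pool$decomposed <- mark_decomposed(pool, config)
    # the true trains generate EMG and torque; the decoders observe
    # imperfectly decomposed copies
    pool$firings_true <- pool$firings
    pool$firings <- lapply(seq_len(nrow(pool)), function(i) {
      if (!pool$decomposed[i]) return(pool$firings_true[[i]])
      corrupt_firings(pool$firings_true[[i]], config$miss_rate,
                      config$false_rate)
    })
    active <- rep(FALSE, floor(duration * config$emg_fs) + 1L)
    act_t <- profile$time[profile$excitation > 0]
    if (length(act_t) > 0) {
      act_idx <- unique(round(act_t * config$emg_fs)) + 1L
      active[act_idx[act_idx <= length(active)]] <- TRUE
    }
    emg <- synthesize_emg(pool, config, duration, active = active)
    torque <- synthesize_torque(pool, config, duration)
    # MVC calibration: 3 s at 100 %MVC with 0.5 s lead-in/out
    mvc_prof <- tibble::tibble(
      time = seq(0, 4, by = 0.001),
      excitation = ifelse(seq(0, 4, by = 0.001) >= 0.5 &
                            seq(0, 4, by = 0.001) <= 3.5, 100, 0)
    )
    mvc_pool <- simulate_spike_trains(generate_pool(config), mvc_prof, config)
    mvc_emg <- synthesize_emg(mvc_pool, config, duration = 4)
    mvc_rms <- compute_mvc(bandpass_emg(mvc_emg, fs = config$emg_fs),
                           fs = config$emg_fs)
    structure(list(
      units = pool, emg = emg, emg_fs = config$emg_fs, torque = torque,
      torque_fs = config$torque_fs, mvc_rms = mvc_rms, profile = profile,
      duration = duration, target_mvc = target_mvc, seed = seed,
      config = config
    ), class = "trial_bundle")
  })
}

# emulate decomposition error: delete each true discharge with probability
# miss_rate and insert spurious discharges (binomial count, uniform over the
# unit's active span)
corrupt_firings <- function(f, miss_rate, false_rate) {
  n <- length(f)
  if (n == 0) return(f)
  keep <- runif(n) >= miss_rate
  n_false <- stats::rbinom(1, n, false_rate)
  extra <- if (n_false > 0) runif(n_false, min(f), max(f)) else numeric(0)
  sort(c(f[keep], extra))
}

# size-biased sampling of the decomposed subset: among units that fired
# enough to be separable, sample without replacement with probability
# proportional to MUAP peak-to-peak amplitude
mark_decomposed <- function(pool, config, min_firings = 20) {
  n <- nrow(pool)
  dec <- rep(TRUE, n)
  nd <- config$n_decomposed
  if (is.null(nd) || nd >= n) return(dec)
  active <- vapply(pool$firings, length, integer(1)) >= min_firings
  if (sum(active) <= nd) return(active)
  # detectability grows sharply with MUAP size: size-biased by p2p^2
  p2p <- vapply(pool$muap, function(w) max(w) - min(w), numeric(1))
  picked <- sample(which(active), nd, prob = p2p[active]^2)
  dec <- rep(FALSE, n)
  dec[picked] <- TRUE
  dec
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat("<trial_bundle>\n")
  n_dec <- if ("decomposed" %in% names(x$units)) sum(x$units$decomposed)
           else nrow(x$units)
  cat(sprintf("  %d motor units (%d decomposed), %.1f s, target %g %%MVC\n",
              nrow(x$units), n_dec, x$duration, x$target_mvc))
  cat(sprintf("  EMG %d samples @ %g Hz; torque %d samples @ %g Hz\n",
              length(x$emg), x$emg_fs, length(x$torque), x$torque_fs))
  cat(sprintf("  MVC reference RMS: %.3g\n", x$mvc_rms))
  invisible(x)
}

#' Crop a trial bundle to a time range
#'
#' Extracts the sub-trial on `[t0, t1]`, re-referencing all times to `t0`.
#' Used to split a two-trapezoid trial into cross-validation folds.
#'
#' @param bundle A `trial_bundle`.
#' @param t0,t1 Crop window (s).
#' @return A `trial_bundle` covering `t1 - t0` seconds.
#' @export
crop_bundle <- function(bundle, t0, t1) {
  ei <- which((seq_along(bundle$emg) - 1) / bundle$emg_fs >= t0 &
                (seq_along(bundle$emg) - 1) / bundle$emg_fs <= t1)
  ti <- which((seq_along(bundle$torque) - 1) / bundle$torque_fs >= t0 &
                (seq_along(bundle$torque) - 1) / bundle$torque_fs <= t1)
  units <- bundle$units
  units$firings <- lapply(units$firings, function(f) f[f >= t0 & f <= t1] - t0)
  prof <- bundle$profile[bundle$profile$time >= t0 & bundle$profile$time <= t1, ]
  prof$time <- prof$time - t0
  out <- bundle
  out$units <- units
  out$emg <- bundle$emg[ei]
  out$torque <- bundle$torque[ti]
  out$profile <- prof
  out$duration <- t1 - t0
  out
}
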