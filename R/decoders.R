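#' Decoder configuration
#'
#' Collects the signal-processing and model-fitting settings shared by the
#' three decoders.
#'
#' @param window,step Moving-window length and step (s) defining the 10 Hz
#'   feature grid.
#' @param torque_lowpass_hz Torque low-pass cutoff (Hz).
#' @param emg_band EMG band-pass edges (Hz).
#' @param kalman_process_var,kalman_measurement_var Kalman noise variances;
#'   `NULL` scales them to the series variance (see [kalman_smooth()]).
#' @param max_lag_s Maximum absolute alignment lag (s).
#' @param max_units Maximum number of motor units retained by the
#'   refinement step (default 10).
#' @param rate_threshold_hz Firing rate defining recruitment for the
#'   recruitment-threshold estimate (Hz).
#' @param ga GA settings from [ga_config()] used when fitting MUDrive with
#'   optimization.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(window = 0.5, step = 0.1, torque_lowpass_hz = 2,
                           emg_band = c(20, 450),
                           kalman_process_var = NULL,
                           kalman_measurement_var = NULL,
                           max_lag_s = 0.5, max_units = 10,
                           rate_threshold_hz = 5, ga = ga_config()) {
  structure(list(
    window = window, step = step, torque_lowpass_hz = torque_lowpass_hz,
    emg_band = emg_band, kalman_process_var = kalman_process_var,
    kalman_measurement_var = kalman_measurement_var, max_lag_s = max_lag_s,
    max_units = max_units, rate_threshold_hz = rate_threshold_hz, ga = ga
  ), class = "decoder_config")
}

smooth_series <- function(series, config) {
  kalman_smooth(series, config$kalman_process_var,
                config$kalman_measurement_var)
}

# ordinary least squares with an intercept; ridge fallback (penalty 1e-8 on
# the standardized slopes) when the design is rank-deficient
ols_fit <- function(X, y, ridge_penalty = 1e-8) {
  X <- as.matrix(X)
  if (any(apply(X, 2, sd) == 0)) abort("degenerate regressor")
  qrX <- qr(cbind(1, X))
  ridge <- qrX$rank < ncol(X) + 1
  if (!ridge) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    beta <- fit$coefficients
    intercept <- beta[1]
    slopes <- beta[-1]
  } else {
    xm <- colMeans(X)
    ym <- mean(y)
    Xc <- sweep(X, 2, xm)
    A <- crossprod(Xc) + ridge_penalty * diag(ncol(X))
    slopes <- drop(solve(A, crossprod(Xc, y - ym)))
    intercept <- ym - sum(xm * slopes)
  }
  fitted <- drop(X %*% slopes) + intercept
  res <- y - fitted
  list(coefficients = slopes, intercept = unname(intercept),
       fitted = fitted, rmse = sqrt(mean(res^2)),
       r_squared = if (var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else NA_real_,
       ridge = ridge)
}

new_decoder_model <- function(method, unit_ids, coefficients, intercept, lag,
                              bounds = NULL, twitches = NULL,
                              train_rmse = NA_real_, r_squared = NA_real_,
                              config = decoder_config()) {
  structure(list(
    method = method, unit_ids = unit_ids, coefficients = coefficients,
    intercept = intercept, lag = lag, bounds = bounds, twitches = twitches,
    train_rmse = train_rmse, r_squared = r_squared, config = config
  ), class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model: %s>\n", x$method))
  if (length(x$unit_ids)) {
    cat(sprintf("  %d retained unit(s): %s\n", length(x$unit_ids),
                paste(x$unit_ids, collapse = ", ")))
  }
  cat(sprintf("  lag %.2f s, intercept %.4g, training RMSE %.4g\n",
              x$lag, x$intercept, x$train_rmse))
  invisible(x)
}

#' Fit the EMG-amplitude (aEMG) decoder
#'
#' Ordinary least squares of the torque reference on the normalized,
#' Kalman-smoothed EMG RMS envelope, after cross-correlation alignment.
#'
#' @param emg_feature Feature series of smoothed EMG amplitude (%MVC).
#' @param torque Torque reference feature series (Nm), index-aligned with
#'   `emg_feature` before lag compensation.
#' @param config A [decoder_config()].
#' @return A `decoder_model`.
#' @export
fit_aemg <- function(emg_feature, torque, config = decoder_config()) {
  al <- align_by_xcorr(emg_feature, torque, max_lag = config$max_lag_s)
  fit <- ols_fit(matrix(al$feature$value, ncol = 1), al$reference$value)
  new_decoder_model("aEMG", unit_ids = integer(0),
                    coefficients = unname(fit$coefficients),
                    intercept = fit$intercept, lag = al$lag,
                    train_rmse = fit$rmse, r_squared = fit$r_squared,
                    config = config)
}

#' Rank units by single-unit torque correlation and retain the best
#'
#' Regresses the torque reference on each unit's smoothed firing rate in
#' turn, ranks units by R-squared and returns the identifiers of the best
#' `max_units` (all units if fewer are available). Ties are broken by unit
#' id for determinism.
#'
#' @param rate_series Named list of smoothed firing-rate feature series
#'   (names are unit ids), index-aligned with `torque`.
#' @param torque Torque reference feature series.
#' @param max_units Number of units to retain (default 10).
#' @return Integer vector of retained unit ids, best first.
#' @export
refine_units <- function(rate_series, torque, max_units = 10) {
  if (length(rate_series) == 0) abort("no units to refine")
  ids <- as.integer(names(rate_series))
  r2 <- vapply(rate_series, function(s) {
    v <- s$value
    if (sd(v) == 0) return(-Inf)
    stats::cor(v, torque$value)^2
  }, numeric(1))
  ord <- order(-r2, ids)
  head(ids[ord], max_units)
}

#' Fit the neural-drive (ND) decoder
#'
#' Multiple linear regression of torque on the retained units' smoothed
#' firing rates: `tau(t) = sum_i a_i FR_i(t) + b`. Exactly collinear rates
#' trigger a ridge fallback with a tiny penalty.
#'
#' @param rate_series Named list of smoothed firing-rate feature series for
#'   the retained units, index-aligned with `torque` (post alignment).
#' @param torque Torque reference feature series.
#' @param lag Alignment lag (s) to store in the model.
#' @param config A [decoder_config()].
#' @return A `decoder_model` with per-unit coefficients.
#' @export
fit_nd <- function(rate_series, torque, lag = 0, config = decoder_config()) {
  if (length(rate_series) == 0) abort("refined unit list is empty")
  X <- do.call(cbind, lapply(rate_series, function(s) s$value))
  colnames(X) <- names(rate_series)
  fit <- ols_fit(X, torque$value)
  if (fit$ridge) {
    warn("collinear firing rates: ridge fallback (penalty 1e-8) used")
  }
  new_decoder_model("ND", unit_ids = as.integer(names(rate_series)),
                    coefficients = stats::setNames(fit$coefficients,
                                                   names(rate_series)),
                    intercept = fit$intercept, lag = lag,
                    train_rmse = fit$rmse, r_squared = fit$r_squared,
                    config = config)
}

#' Estimate a unit's recruitment threshold from EMG amplitude
#'
#' The recruitment threshold is defined as the EMG amplitude, in %MVC, in a
#' 200-ms window centered at the time the unit's firing rate first exceeds
#' 5 Hz.
#'
#' @param emg Band-pass filtered EMG trace.
#' @param rate Firing-rate feature series of the unit (Hz).
#' @param mvc_rms MVC reference RMS (EMG units).
#' @param fs EMG sampling rate (Hz).
#' @param rate_threshold_hz Recruitment rate threshold (Hz).
#' @param rt_window Window length around the recruitment time (s).
#' @return Recruitment threshold in %MVC, or `NA` (with attribute `reason`)
#'   if the rate never exceeds the threshold.
#' @export
compute_rt <- function(emg, rate, mvc_rms, fs = 2222, rate_threshold_hz = 5,
                       rt_window = 0.2) {
  hit <- which(rate$value > rate_threshold_hz)
  if (length(hit) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no recruitment detected"
    return(out)
  }
  t_star <- rate$time[hit[1]]
  i0 <- max(1L, round((t_star - rt_window / 2) * fs) + 1L)
  i1 <- min(length(emg), round((t_star + rt_window / 2) * fs) + 1L)
  rms <- sqrt(mean(emg[i0:i1]^2))
  100 * rms / mvc_rms
}

# windowed + Kalman-smoothed MUDrive feature on the common grid
mudrive_feature <- function(firings, twitches, duration, fs,
                            config = decoder_config()) {
  x <- mudrive_signal(firings, twitches$p, twitches$tr, twitches$thr,
                      duration = duration, fs = fs)
  smooth_series(window_stat(x, fs, duration = duration,
                            window = config$window, step = config$step,
                            stat = "mean"), config)
}

#' Fit the MUDrive (twitch-convolution) decoder for given pool bounds
#'
#' Rescales the pool bounds into per-unit twitch parameters via the units'
#' recruitment thresholds, computes the MUDrive signal (gain-weighted
#' twitch trains summed over the retained units), windows and
#' Kalman-smooths it, aligns it with the torque reference and fits a simple
#' linear regression. Because of the final regression, predictions are
#' invariant to a uniform scaling of the peak-force range.
#'
#' @param units Tibble of retained units with columns `id`, `firings` and
#'   `rt` (estimated recruitment thresholds, %MVC).
#' @param bounds A [pool_bounds()].
#' @param torque Torque reference feature series.
#' @param duration Trial duration (s).
#' @param fs Sampling rate for the internal force signal (Hz); the torque
#'   sampling rate is the natural choice.
#' @param config A [decoder_config()].
#' @return A `decoder_model` storing the bounds, per-unit twitch
#'   parameters, slope, intercept and lag.
#' @export
fit_mudrive <- function(units, bounds, torque, duration, fs = 100,
                        config = decoder_config()) {
  units <- units[!is.na(units$rt), ]
  if (nrow(units) == 0) abort("no unit with a defined recruitment threshold")
  tw <- rescale_twitch_params(units$rt, bounds)
  feat <- mudrive_feature(units$firings, tw, duration, fs, config)
  al <- align_by_xcorr(feat, torque, max_lag = config$max_lag_s)
  fit <- ols_fit(matrix(al$feature$value, ncol = 1), al$reference$value)
  new_decoder_model("MUDrive", unit_ids = units$id,
                    coefficients = unname(fit$coefficients),
                    intercept = fit$intercept, lag = al$lag,
                    bounds = bounds,
                    twitches = dplyr::bind_cols(tibble::tibble(id = units$id,
                                                               rt = units$rt), tw),
                    train_rmse = fit$rmse, r_squared = fit$r_squared,
                    config = config)
}

# ---- full single-fold training pipeline -----------------------------------

# Precompute everything the decoders share on one fold: torque reference,
# filtered EMG, aEMG feature, validation reports, smoothed rates of accepted
# units.
prepare_fold <- function(bundle, config = decoder_config()) {
  duration <- bundle$duration
  torque_ref <- preprocess_torque(bundle$torque, fs = bundle$torque_fs,
                                  duration = duration,
                                  cutoff_hz = config$torque_lowpass_hz,
                                  window = config$window, step = config$step)
  femg <- bandpass_emg(bundle$emg, fs = bundle$emg_fs,
                       band = config$emg_band)
  aemg <- smooth_series(
    normalize_to_mvc(moving_rms(femg, fs = bundle$emg_fs,
                                duration = duration,
                                window = config$window, step = config$step),
                     bundle$mvc_rms), config)
  units <- bundle$units
  if ("decomposed" %in% names(units)) units <- units[units$decomposed, ]
  val <- purrr::map(seq_len(nrow(units)), function(i) {
    validate_mu(femg, units$firings[[i]], units$muap[[i]],
                fs = bundle$emg_fs)
  })
  val <- dplyr::bind_cols(tibble::tibble(id = units$id),
                          dplyr::bind_rows(val))
  acc_ids <- val$id[val$accepted]
  acc <- units[units$id %in% acc_ids, ]
  raw_rates <- lapply(acc$firings, function(f) {
    firing_rate_series(f, duration, window = config$window,
                       step = config$step)
  })
  rates <- stats::setNames(lapply(raw_rates, smooth_series, config = config),
                           acc$id)
  raw_rates <- stats::setNames(raw_rates, acc$id)
  list(bundle = bundle, duration = duration, torque_ref = torque_ref,
       femg = femg, aemg = aemg, validation = val, accepted = acc,
       rates = rates, raw_rates = raw_rates, config = config)
}

# common alignment lag for rate-based decoders: lag of the summed smoothed
# rate against the torque reference
rate_lag <- function(prep) {
  if (length(prep$rates) == 0) return(0L)
  total <- Reduce(`+`, lapply(prep$rates, `[[`, "value"))
  best_lag(total, prep$torque_ref$value,
           max_l = round(prep$config$max_lag_s / prep$config$step))
}

# refined (top max_units) units with lag-aligned smoothed rates
refined_rates <- function(prep) {
  if (length(prep$rates) == 0) abort("no accepted motor units")
  lag_steps <- rate_lag(prep)
  shifted <- lapply(prep$rates, function(s) {
    apply_lag(s, prep$torque_ref, lag_steps)$feature
  })
  torque_trim <- apply_lag(prep$rates[[1]], prep$torque_ref,
                           lag_steps)$reference
  keep <- refine_units(shifted, torque_trim,
                       max_units = prep$config$max_units)
  list(ids = keep, rates = shifted[as.character(keep)],
       torque = torque_trim, lag_steps = lag_steps,
       lag = lag_steps * prep$config$step)
}

#' Fit a decoder on one training fold of a trial bundle
#'
#' Runs the full training pipeline for one of the three decoding methods on
#' a (cropped) trial bundle: torque preprocessing, EMG filtering, STA
#' validation of the decomposed units, feature construction, unit
#' refinement (ND/MUDrive), recruitment-threshold estimation and
#' genetic-algorithm bound optimization (MUDrive), alignment and
#' regression.
#'
#' @param bundle A `trial_bundle` (typically one cross-validation fold).
#' @param method One of `"aEMG"`, `"ND"`, `"MUDrive"`.
#' @param config A [decoder_config()].
#' @param seed Integer seed for the GA (MUDrive only).
#' @param optimize Logical; optimize the MUDrive pool bounds with the GA
#'   (default `TRUE`). When `FALSE`, `bounds` is used as-is.
#' @param bounds Pool bounds used when `optimize = FALSE` (default the
#'   constraint-box midpoints).
#' @return A `decoder_model`.
#' @export
fit_decoder <- function(bundle, method = c("aEMG", "ND", "MUDrive"),
                        config = decoder_config(), seed = 1,
                        optimize = TRUE, bounds = midpoint_bounds()) {
  method <- match.arg(method)
  prep <- prepare_fold(bundle, config)
  if (method == "aEMG") {
    return(fit_aemg(prep$aemg, prep$torque_ref, config))
  }
  ref <- refined_rates(prep)
  if (method == "ND") {
    return(fit_nd(ref$rates, ref$torque, lag = ref$lag, config = config))
  }
  units <- mudrive_units(prep, ref)
  if (optimize) {
    opt <- ga_optimize(prep, units,
                       mask = rep(TRUE, 5), control = config$ga,
                       seed = seed)
    bounds <- opt$best_bounds
  }
  fit_mudrive(units, bounds, prep$torque_ref, prep$duration,
              fs = bundle$torque_fs, config = config)
}

# retained units with estimated recruitment thresholds (MUDrive input)
mudrive_units <- function(prep, ref = refined_rates(prep)) {
  acc <- prep$accepted
  keep <- acc[match(ref$ids, acc$id), ]
  rt <- vapply(as.character(keep$id), function(id) {
    compute_rt(prep$femg, prep$raw_rates[[id]], prep$bundle$mvc_rms,
               fs = prep$bundle$emg_fs,
               rate_threshold_hz = prep$config$rate_threshold_hz)
  }, numeric(1))
  out <- tibble::tibble(id = keep$id, firings = keep$firings, rt = rt)
  out[!is.na(out$rt), ]
}

#' Predict torque from a fitted decoder on a trial bundle
#'
#' Rebuilds the model's input features from the bundle, applies the stored
#' alignment lag and linear map, and returns the torque estimate on the
#' common feature grid (trimmed by the lag).
#'
#' @param object A `decoder_model`.
#' @param bundle A `trial_bundle` (e.g. the held-out fold).
#' @param ... Unused.
#' @return A feature series tibble (`time`, `value` in Nm).
#' @export
predict.decoder_model <- function(object, bundle, ...) {
  config <- object$config
  duration <- bundle$duration
  if (object$method == "aEMG") {
    femg <- bandpass_emg(bundle$emg, fs = bundle$emg_fs,
                         band = config$emg_band)
    feat <- smooth_series(
      normalize_to_mvc(moving_rms(femg, fs = bundle$emg_fs,
                                  duration = duration,
                                  window = config$window,
                                  step = config$step),
                       bundle$mvc_rms), config)
    X <- matrix(feat$value, ncol = 1)
    times <- feat$time
  } else if (object$method == "ND") {
    miss <- setdiff(object$unit_ids, bundle$units$id)
    if (length(miss) > 0) {
      abort(sprintf("bundle is missing retained unit(s): %s",
                    paste(miss, collapse = ", ")))
    }
    rows <- match(object$unit_ids, bundle$units$id)
    rates <- lapply(bundle$units$firings[rows], function(f) {
      smooth_series(firing_rate_series(f, duration, window = config$window,
                                       step = config$step), config)
    })
    X <- do.call(cbind, lapply(rates, `[[`, "value"))
    times <- rates[[1]]$time
  } else {
    miss <- setdiff(object$unit_ids, bundle$units$id)
    if (length(miss) > 0) {
      abort(sprintf("bundle is missing retained unit(s): %s",
                    paste(miss, collapse = ", ")))
    }
    rows <- match(object$unit_ids, bundle$units$id)
    feat <- mudrive_feature(bundle$units$firings[rows], object$twitches,
                            duration, fs = bundle$torque_fs, config)
    X <- matrix(feat$value, ncol = 1)
    times <- feat$time
  }
  pred <- drop(X %*% object$coefficients) + object$intercept
  series <- new_feature_series(times, pred)
  # advance the feature by the stored lag: estimate at time t uses the
  # feature observed at t + lag
  lag_steps <- round(object$lag / config$step)
  n <- length(pred)
  if (lag_steps >= 0) {
    idx <- seq(1 + lag_steps, n)
    new_feature_series(times[seq(1, n - lag_steps)], pred[idx])
  } else {
    idx <- seq(1, n + lag_steps)
    new_feature_series(times[seq(1 - lag_steps, n)], pred[idx])
  }
}
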