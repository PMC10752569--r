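#' @name feature-series
#' @title Feature series on the common 10 Hz grid
#'
#' @description All decoder inputs and the torque reference live on one
#' uniformly spaced grid of window centers: 0.5-s windows advanced in
#' 0.1-s steps, so the grid runs from `window/2` to `duration - window/2`
#' at 10 Hz. A feature series is a tibble with columns `time` (s, window
#' centers) and `value` (feature units). Any two feature series computed
#' from the same trial are index-aligned.
NULL

# window centers shared by every windowed operator
feature_grid <- function(duration, window = 0.5, step = 0.1) {
  if (duration < window) abort("trace shorter than one window")
  seq(window / 2, duration - window / 2 + 1e-9, by = step)
}

new_feature_series <- function(time, value) {
  tibble::new_tibble(list(time = as.numeric(time), value = as.numeric(value)),
                     nrow = length(time))
}

# windowed statistic over half-open windows [c - w/2, c + w/2)
# stat: "mean", "rms" or "count"
window_stat <- function(x, fs, duration = NULL, window = 0.5, step = 0.1,
                        stat = "mean") {
  n <- length(x)
  if (is.null(duration)) duration <- n / fs
  centers <- feature_grid(duration, window, step)
  # sample k (1-based) sits at time (k - 1) / fs
  lo <- pmax(ceiling((centers - window / 2) * fs - 1e-9) + 1L, 1L)
  hi <- pmin(ceiling((centers + window / 2) * fs - 1e-9), n)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  cnt <- pmax(hi - lo + 1L, 0L)
  s1 <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- switch(stat,
    mean = ifelse(cnt > 0, s1 / cnt, 0),
    rms = ifelse(cnt > 0, sqrt(s2 / cnt), 0),
    abort("unknown window statistic")
  )
  new_feature_series(centers, v)
}

#' Preprocess raw torque into the 10 Hz reference series
#'
#' Removes the DC offset (mean of the first second), low-pass filters at
#' 2 Hz (4th-order Butterworth, applied zero-phase) and averages in a
#' moving window (0.5 s, 0.1 s step) to produce the torque reference the
#' decoders are regressed against.
#'
#' @param torque Numeric vector, raw torque samples.
#' @param fs Sampling rate of `torque` in Hz (default 100).
#' @param duration Trial duration in s; defaults to `length(torque) / fs`.
#'   Passing the trial duration shared with the EMG trace guarantees an
#'   index-aligned grid.
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param window,step Moving-window length and step (s).
#'
#' @return A feature series tibble (`time`, `value`), value in the input
#'   torque units.
#' @examples
#' tq <- sin(seq(0, 2 * pi, length.out = 500)) + 5
#' preprocess_torque(tq, fs = 100)
#' @export
preprocess_torque <- function(torque, fs = 100, duration = NULL,
                              cutoff_hz = 2, window = 0.5, step = 0.1) {
  if (length(torque) < 2 * fs) abort("torque trace must be at least 2 s long")
  offset <- mean(torque[seq_len(round(fs))])
  x <- torque - offset
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, x)
  window_stat(x, fs, duration = duration, window = window, step = step,
              stat = "mean")
}

#' Band-pass filter raw EMG
#'
#' Applies a 20--450 Hz Butterworth band-pass (realized as a cascade of a
#' 4th-order high-pass and a 4th-order low-pass, each applied zero-phase)
#' to remove baseline drift and out-of-band noise.
#'
#' @param emg Numeric vector of raw EMG samples.
#' @param fs Sampling rate in Hz (default 2222).
#' @param band Length-2 numeric, pass band edges in Hz.
#' @return Numeric vector, filtered EMG (same length).
#' @examples
#' x <- rnorm(5000)
#' y <- bandpass_emg(x)
#' @export
bandpass_emg <- function(emg, fs = 2222, band = c(20, 450)) {
  hp <- signal::butter(4, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, emg))
}

#' Moving-window RMS envelope
#'
#' Root-mean-square amplitude of a trace in centered 0.5-s windows advanced
#' in 0.1-s steps — the aEMG amplitude estimator.
#'
#' @inheritParams preprocess_torque
#' @param x Numeric vector (typically band-passed EMG).
#' @return A feature series tibble (`time`, `value`).
#' @examples
#' moving_rms(sin(seq(0, 100, by = 1 / 2222) * 2 * pi * 50), fs = 2222)
#' @export
moving_rms <- function(x, fs, duration = NULL, window = 0.5, step = 0.1) {
  if (length(x) < window * fs) abort("trace shorter than one window")
  window_stat(x, fs, duration = duration, window = window, step = step,
              stat = "rms")
}

#' Smoothed firing-rate series of one motor unit
#'
#' Counts discharges in centered 0.5-s windows advanced in 0.1-s steps and
#' divides by the window length, giving an instantaneous firing-rate
#' estimate in Hz on the common feature grid.
#'
#' @param firings Numeric vector of discharge times (s), sorted ascending.
#' @param duration Trial duration (s), defining the grid.
#' @param window,step Window length and step (s).
#' @return A feature series tibble (`time`, `value` in Hz).
#' @examples
#' firing_rate_series(c(1.0, 1.1, 1.2, 1.35, 1.42), duration = 3)
#' @export
firing_rate_series <- function(firings, duration, window = 0.5, step = 0.1) {
  centers <- feature_grid(duration, window, step)
  if (length(firings) == 0) {
    return(new_feature_series(centers, rep(0, length(centers))))
  }
  if (is.unsorted(firings)) abort("`firings` must be sorted ascending")
  # half-open window [c - w/2, c + w/2)
  n_in <- findInterval(centers + window / 2, firings, left.open = TRUE) -
    findInterval(centers - window / 2, firings, left.open = TRUE)
  new_feature_series(centers, n_in / window)
}

#' Kalman-smooth a feature series
#'
#' Runs a scalar random-walk Kalman filter (identity state transition and
#' observation) forward over the series. Default noise variances are
#' proportional to the series variance, which makes the smoother
#' scale-equivariant: smoothing `a * x` gives `a *` smoothing of `x`.
#'
#' @param series A feature series tibble (`time`, `value`).
#' @param process_var Process-noise variance; default `1e-2 * var(value)`.
#' @param measurement_var Measurement-noise variance; default
#'   `1e-1 * var(value)`. The default ratio gives a steady-state gain of
#'   about 0.27 per 0.1-s step (effective time constant about 0.3 s),
#'   enough to suppress envelope noise without distorting the 2-s ramps.
#' @return A feature series tibble on the same grid.
#' @examples
#' s <- tibble::tibble(time = seq(0.25, 10, 0.1), value = rnorm(98))
#' kalman_smooth(s)
#' @export
kalman_smooth <- function(series, process_var = NULL, measurement_var = NULL) {
  z <- series$value
  v <- stats::var(z)
  if (!is.finite(v) || v == 0) v <- 1
  if (is.null(process_var)) process_var <- 1e-2 * v
  if (is.null(measurement_var)) measurement_var <- 1e-1 * v
  if (process_var <= 0 || measurement_var <= 0) {
    abort("noise variances must be positive")
  }
  n <- length(z)
  out <- numeric(n)
  x <- z[1]
  p <- measurement_var
  out[1] <- x
  if (n > 1) {
    for (k in 2:n) {
      pp <- p + process_var
      kg <- pp / (pp + measurement_var)
      x <- x + kg * (z[k] - x)
      p <- (1 - kg) * pp
      out[k] <- x
    }
  }
  new_feature_series(series$time, out)
}

#' Normalize an amplitude series to %MVC
#'
#' Divides by the maximum-voluntary-contraction reference RMS and expresses
#' the result as a percentage, so EMG amplitude becomes muscle activation
#' in %MVC. Normalization to MVC mitigates between-condition differences in
#' absolute amplitude caused by MUAP cancellation and electrode placement.
#'
#' @param series Feature series (`time`, `value` in volts).
#' @param mvc_rms MVC reference RMS (volts); must be positive.
#' @return Feature series with `value` in %MVC.
#' @examples
#' s <- tibble::tibble(time = 1:3 / 10, value = c(0, 0.5, 1))
#' normalize_to_mvc(s, mvc_rms = 1)
#' @export
normalize_to_mvc <- function(series, mvc_rms) {
  if (!is.numeric(mvc_rms) || length(mvc_rms) != 1 || mvc_rms <= 0) {
    abort("`mvc_rms` must be a positive scalar")
  }
  new_feature_series(series$time, series$value * 100 / mvc_rms)
}

#' MVC reference from a calibration contraction
#'
#' The MVC reference is the largest root-mean-square amplitude over all
#' sliding 0.5-s windows of the (filtered) EMG recorded during a maximal
#' contraction. The window slides sample by sample.
#'
#' @param emg Numeric vector of filtered EMG samples.
#' @param fs Sampling rate (Hz).
#' @param window Window length (s).
#' @return Scalar MVC RMS in the EMG units.
#' @examples
#' compute_mvc(rnorm(5000), fs = 2222)
#' @export
compute_mvc <- function(emg, fs = 2222, window = 0.5) {
  n <- length(emg)
  w <- round(window * fs)
  if (n < w) abort("trace shorter than one window")
  cs2 <- cumsum(c(0, emg^2))
  ms <- (cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]) / w
  sqrt(max(ms))
}

#' Align a feature series to a reference by cross-correlation
#'
#' Finds the lag (within `max_lag`, on the 0.1-s feature grid) that
#' maximizes the Pearson correlation between the feature and the reference,
#' shifts the feature by that lag and trims both series to their common
#' support. A positive lag means the feature lags the reference (e.g.
#' electromechanical delay) and is advanced to compensate. Ties are broken
#' toward the smallest absolute lag; a degenerate (constant) feature gets
#' lag 0.
#'
#' @param feature,reference Feature series tibbles on the same grid.
#' @param max_lag Maximum absolute lag searched (s).
#' @return A list with elements `lag` (s), `feature` and `reference`
#'   (trimmed, index-aligned feature series).
#' @examples
#' r <- tibble::tibble(time = seq(0.25, 20, 0.1), value = sin(seq(0.25, 20, 0.1)))
#' f <- tibble::tibble(time = r$time, value = sin(r$time - 0.3))
#' align_by_xcorr(f, r)$lag
#' @export
align_by_xcorr <- function(feature, reference, max_lag = 0.5) {
  if (max_lag < 0) abort("`max_lag` must be nonnegative")
  step <- median(diff(reference$time))
  lag <- best_lag(feature$value, reference$value, max_l = round(max_lag / step))
  shifted <- apply_lag(feature, reference, lag_steps = lag)
  list(lag = lag * step, feature = shifted$feature, reference = shifted$reference)
}

# integer-lag Pearson correlation search; positive lag means the feature is
# delayed relative to the reference
best_lag <- function(f, r, max_l) {
  lags <- seq(-max_l, max_l)
  n <- min(length(f), length(r))
  scores <- vapply(lags, function(l) {
    if (l >= 0) {
      fi <- seq(1 + l, n)
      ri <- seq(1, n - l)
    } else {
      fi <- seq(1, n + l)
      ri <- seq(1 - l, n)
    }
    if (length(fi) < 3) return(-Inf)
    fv <- f[fi]
    rv <- r[ri]
    if (sd(fv) == 0 || sd(rv) == 0) return(-Inf)
    stats::cor(fv, rv)
  }, numeric(1))
  if (all(!is.finite(scores))) return(0L)
  best <- max(scores)
  cand <- lags[scores >= best - 1e-12]
  cand[which.min(abs(cand))]
}

# shift feature by an integer number of grid steps and trim both series to
# the overlap; time axis of the reference is kept
apply_lag <- function(feature, reference, lag_steps) {
  n <- min(nrow(feature), nrow(reference))
  l <- lag_steps
  if (l >= 0) {
    fi <- seq(1 + l, n)
    ri <- seq(1, n - l)
  } else {
    fi <- seq(1, n + l)
    ri <- seq(1 - l, n)
  }
  list(
    feature = new_feature_series(reference$time[ri], feature$value[fi]),
    reference = reference[ri, ]
  )
}
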