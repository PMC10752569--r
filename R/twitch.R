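#' Linear rescaling of pool bounds into per-unit twitch parameters
#'
#' Following the size principle, each unit's twitch parameters are obtained
#' by linearly rescaling the pool-level ranges according to its recruitment
#' threshold: with `r_i = (RT_i - min RT) / (max RT - min RT)`,
#' `P_i = p_min + r_i (p_max - p_min)` and likewise for rise time and
#' half-relaxation time. The lowest-threshold unit gets the minimum of each
#' range and the highest-threshold unit the maximum, so later-recruited
#' units produce larger, slower twitches. A single-unit pool (or a pool
#' with all thresholds equal) gets `r = 0`.
#'
#' @param rts Numeric vector of recruitment thresholds (%MVC).
#' @param bounds A [pool_bounds()].
#' @return A tibble with columns `p` (arb. force), `tr` (s), `thr` (s),
#'   one row per unit.
#' @examples
#' rescale_twitch_params(c(2, 8, 32), pool_bounds())
#' @export
rescale_twitch_params <- function(rts, bounds) {
  if (length(rts) < 1) abort("need at least one recruitment threshold")
  span <- max(rts) - min(rts)
  r <- if (span > 0) (rts - min(rts)) / span else rep(0, length(rts))
  tibble::tibble(
    p = bounds$p_min + r * (bounds$p_max - bounds$p_min),
    tr = bounds$tr_min + r * (bounds$tr_max - bounds$tr_min),
    thr = bounds$thr_min + r * (bounds$thr_max - bounds$thr_min)
  )
}

#' Force twitch value at arbitrary times (closed form)
#'
#' The modeled twitch rises as a critically damped impulse response,
#' `f(t) = P (t / Tr) exp(1 - t / Tr)` for `t <= Tr`, reaching its unique
#' maximum `P` exactly at the rise time `Tr`, and decays exponentially as
#' `f(t) = P 2^(-(t - Tr) / Thr)` afterwards, so that the force has fallen
#' to `P / 2` exactly one half-relaxation time after the peak.
#'
#' @param t Numeric vector of times since the discharge (s).
#' @param p Peak twitch force (arb. units).
#' @param tr Rise time (s).
#' @param thr Half-relaxation time (s).
#' @return Twitch force at `t` (same units as `p`).
#' @examples
#' twitch_value(c(0, 0.05, 0.08), p = 10, tr = 0.05, thr = 0.03)
#' @export
twitch_value <- function(t, p, tr, thr) {
  if (p <= 0 || tr <= 0 || thr <= 0) abort("twitch parameters must be positive")
  ifelse(t < 0, 0,
         ifelse(t <= tr,
                p * (t / tr) * exp(1 - t / tr),
                p * 2^(-(t - tr) / thr)))
}

#' Sampled twitch waveform
#'
#' Samples [twitch_value()] on a uniform grid starting at the discharge
#' instant and truncates the tail once the force has decayed below
#' `1e-4 * p`.
#'
#' @inheritParams twitch_value
#' @param fs Sampling rate (Hz).
#' @return Numeric vector; element `k` is the force `(k - 1) / fs` seconds
#'   after the discharge.
#' @examples
#' w <- twitch_waveform(p = 10, tr = 0.05, thr = 0.03, fs = 1000)
#' max(w)
#' @export
twitch_waveform <- function(p, tr, thr, fs) {
  if (p <= 0 || tr <= 0 || thr <= 0) abort("twitch parameters must be positive")
  # decay falls below 1e-4 P at tr + thr * log2(1e4)
  t_max <- tr + thr * log2(1e4)
  t <- seq(0, t_max, by = 1 / fs)
  twitch_value(t, p, tr, thr)
}

#' Rate-dependent gain of a twitch
#'
#' At high firing rates successive twitches fuse and the per-spike force
#' gain drops below its isolated-twitch value. The gain is a sigmoidal
#' function of the normalized stimulus rate `x = Tr / ISI`: unity for
#' `x <= 0.4` and `(S(x)/x) / (S(0.4)/0.4)` with `S(x) = 1 - exp(-2 x^3)`
#' above the knee, continuous at `x = 0.4`. The first spike of a train
#' (no preceding ISI) gets gain 1.
#'
#' @param tr Twitch rise time (s).
#' @param isi Preceding inter-spike interval (s); may be a vector.
#' @return Dimensionless gain in (0, 1].
#' @examples
#' spike_gain(0.05, c(1, 0.1, 0.05))
#' @export
spike_gain <- function(tr, isi) {
  if (any(isi <= 0)) abort("`isi` must be positive")
  x <- tr / isi
  s <- function(x) 1 - exp(-2 * x^3)
  norm <- s(0.4) / 0.4
  ifelse(x <= 0.4, 1, (s(x) / x) / norm)
}

# per-spike gains for one train: first spike 1, then gain of preceding ISI
train_gains <- function(firings, tr) {
  n <- length(firings)
  if (n == 0) return(numeric(0))
  if (n == 1) return(1)
  c(1, spike_gain(tr, diff(firings)))
}

#' MUDrive signal: summed gain-weighted twitch trains
#'
#' For each unit, every spike contributes its twitch waveform shifted to
#' the spike time and scaled by the rate-dependent gain of the preceding
#' inter-spike interval; unit contributions are summed across the pool.
#' The result is the modeled force ("MUDrive") signal at `fs`; callers
#' window (0.5 s / 0.1 s) and Kalman-smooth it into a feature series.
#'
#' @param firings List of numeric vectors, discharge times per unit (s).
#' @param p,tr,thr Numeric vectors of per-unit twitch parameters.
#' @param duration Signal duration (s).
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of length `floor(duration * fs) + 1`.
#' @examples
#' mudrive_signal(list(c(0.1, 0.2)), p = 10, tr = 0.05, thr = 0.03,
#'                duration = 1, fs = 100)
#' @export
mudrive_signal <- function(firings, p, tr, thr, duration, fs) {
  n <- floor(duration * fs) + 1L
  out <- numeric(n)
  for (u in seq_along(firings)) {
    f <- firings[[u]]
    if (length(f) == 0) next
    w <- twitch_waveform(p[u], tr[u], thr[u], fs)
    g <- train_gains(f, tr[u])
    # gain-weighted impulse train convolved with the twitch kernel
    imp <- numeric(n)
    idx <- round(f * fs) + 1L
    keep <- idx >= 1L & idx <= n
    for (k in which(keep)) imp[idx[k]] <- imp[idx[k]] + g[k]
    # FFT convolution padded to a 2-3-5-smooth length
    lw <- length(w)
    M <- stats::nextn(n + lw - 1L, c(2, 3, 5))
    conv <- Re(stats::fft(stats::fft(c(imp, numeric(M - n))) *
                            stats::fft(c(w, numeric(M - lw))),
                          inverse = TRUE)) / M
    out <- out + conv[seq_len(n)]
  }
  out
}
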