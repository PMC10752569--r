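#' Trapezoidal excitation profile
#'
#' Builds the piecewise-linear excitation profile of an isometric
#' profile-tracking trial: a 5-s quiescent period, then `n_trapezoids`
#' trapezoids each ramping at `ramp_rate` %MVC/s up to `target_mvc`,
#' holding for `hold_s` seconds and ramping back down, with `rest_s`
#' seconds of rest between trapezoids and a short tail at the end.
#'
#' @param target_mvc Target excitation level at the plateau (%MVC).
#' @param n_trapezoids Number of trapezoids in the trial.
#' @param ramp_rate Ramp slope magnitude (%MVC per second).
#' @param hold_s Plateau (steady-state) duration in seconds.
#' @param quiescent_s Initial quiescent period in seconds.
#' @param rest_s Rest between successive trapezoids in seconds.
#' @param tail_s Trailing rest after the last trapezoid in seconds.
#' @param dt Sampling step of the returned profile (s).
#'
#' @return A tibble with columns `time` (s), `excitation` (%MVC) and
#'   `segment` (one of `"quiescent"`, `"ramp_up"`, `"hold"`, `"ramp_down"`,
#'   `"rest"`), carrying a `"trapezoids"` attribute: a tibble with the
#'   start/end time of each trapezoid.
#' @examples
#' prof <- trapezoid_profile(20, n_trapezoids = 1)
#' range(prof$excitation)
#' attr(prof, "trapezoids")
#' @export
trapezoid_profile <- function(target_mvc, n_trapezoids = 2, ramp_rate = 10,
                              hold_s = 12, quiescent_s = 5, rest_s = 10,
                              tail_s = 5, dt = 0.001) {
  if (!is.numeric(target_mvc) || target_mvc <= 0) {
    abort("`target_mvc` must be positive.")
  }
  if (!is.numeric(ramp_rate) || ramp_rate <= 0) {
    abort("`ramp_rate` must be positive.")
  }
  if (n_trapezoids < 1) abort("`n_trapezoids` must be at least 1.")

  ramp_s <- target_mvc / ramp_rate
  # breakpoints (time, excitation) plus the segment label that starts there
  bp_t <- 0
  bp_e <- 0
  seg <- character(0)
  t <- quiescent_s
  seg <- c(seg, "quiescent")
  trap_start <- numeric(n_trapezoids)
  trap_end <- numeric(n_trapezoids)
  for (k in seq_len(n_trapezoids)) {
    trap_start[k] <- t
    bp_t <- c(bp_t, t, t + ramp_s, t + ramp_s + hold_s, t + 2 * ramp_s + hold_s)
    bp_e <- c(bp_e, 0, target_mvc, target_mvc, 0)
    seg <- c(seg, "ramp_up", "hold", "ramp_down",
             if (k < n_trapezoids) "rest" else "rest")
    t <- t + 2 * ramp_s + hold_s
    trap_end[k] <- t
    t <- t + if (k < n_trapezoids) rest_s else tail_s
  }
  t_end <- t
  times <- seq(0, t_end, by = dt)
  excitation <- stats::approx(bp_t, bp_e, xout = times, rule = 2)$y
  seg_idx <- findInterval(times, bp_t[-1], left.open = TRUE) + 1L
  seg_idx <- pmin(seg_idx, length(seg))
  out <- tibble::tibble(
    time = times,
    excitation = excitation,
    segment = seg[seg_idx]
  )
  attr(out, "trapezoids") <- tibble::tibble(
    trapezoid = seq_len(n_trapezoids), start = trap_start, end = trap_end
  )
  attr(out, "target_mvc") <- target_mvc
  attr(out, "ramp_rate") <- ramp_rate
  out
}
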