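#' Spike-triggered average MUAP template
#'
#' Stacks 80-ms windows of the filtered EMG centered at every discharge of
#' a unit and averages them, estimating the unit's MUAP waveform. Firings
#' whose window would run past either end of the trace are skipped (their
#' count is reported as an attribute).
#'
#' @param emg Numeric vector of band-pass filtered EMG.
#' @param firings Discharge times (s).
#' @param fs EMG sampling rate (Hz).
#' @param window STA window length (s), default 80 ms.
#' @return Numeric vector of `round(window * fs)` samples, with attributes
#'   `n_used` and `n_skipped`.
#' @export
sta_template <- function(emg, firings, fs = 2222, window = 0.080) {
  n <- length(emg)
  lw <- round(window * fs)
  off <- -(lw %/% 2)
  centers <- round(firings * fs) + 1L
  starts <- centers + off
  ok <- starts >= 1L & (starts + lw - 1L) <= n
  if (!any(ok)) abort("no firing has full window support in the trace")
  acc <- numeric(lw)
  for (s in starts[ok]) acc <- acc + emg[s:(s + lw - 1L)]
  out <- acc / sum(ok)
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

# peak normalized cross-correlation between two waveforms. The shorter
# waveform is zero-padded (centered) to the longer's length and the
# correlation is normalized over the FULL vectors, so energy anywhere in
# the window that the template does not explain counts against the match.
# The alignment search is limited to +/- max_shift samples around center.
peak_ncc <- function(a, b, max_shift = 0L) {
  if (length(b) > length(a)) {
    tmp <- a; a <- b; b <- tmp
  }
  la <- length(a); lb <- length(b)
  pad <- la - lb
  b_pad <- c(numeric(pad %/% 2), b, numeric(pad - pad %/% 2))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b_pad^2))
  if (na == 0 || nb == 0) return(0)
  best <- 0
  for (s in seq(-max_shift, max_shift)) {
    bs <- if (s >= 0) c(numeric(s), b_pad[seq_len(la - s)])
          else c(b_pad[(1 - s):la], numeric(-s))
    r <- abs(sum(a * bs)) / (na * nb)
    if (r > best) best <- r
  }
  best
}

#' Validate a decomposed motor unit by spike-triggered averaging
#'
#' Two-step validation of a decomposed unit. (1) Accuracy: the whole-trial
#' STA of the filtered EMG is compared with the decomposed MUAP template;
#' the squared peak normalized cross-correlation (over alignment shifts)
#' must exceed `r2_threshold`. (2) Stability: STAs are recomputed in a
#' moving window over the trial (8-s window, 4-s step, segments with at
#' least `min_firings` usable discharges); the coefficient of variation of
#' their peak-to-peak amplitudes must stay below `cv_threshold`. Both
#' checks are invariant to a global EMG gain.
#'
#' @param emg Band-pass filtered EMG trace.
#' @param firings Discharge times (s).
#' @param template Decomposed MUAP template (EMG sampling rate).
#' @param fs EMG sampling rate (Hz).
#' @param seg_window,seg_step Moving-window length and step for the
#'   stability check (s).
#' @param sta_window STA window length (s).
#' @param r2_threshold Acceptance threshold on the squared peak normalized
#'   cross-correlation (default 0.6).
#' @param cv_threshold Rejection threshold on the peak-to-peak CV
#'   (default 0.5).
#' @param min_firings Minimum usable firings for a segment STA to count.
#' @return A one-row tibble: `r_squared`, `p2p_cv`, `n_segments`,
#'   `accepted`, `reason` (`NA` when accepted).
#' @examples
#' \dontrun{
#' validate_mu(emg, firings, template)
#' }
#' @export
validate_mu <- function(emg, firings, template, fs = 2222,
                        seg_window = 8, seg_step = 4, sta_window = 0.080,
                        r2_threshold = 0.6, cv_threshold = 0.5,
                        min_firings = 4) {
  fail <- function(r2, cv, nseg, reason) {
    tibble::tibble(r_squared = r2, p2p_cv = cv, n_segments = nseg,
                   accepted = FALSE, reason = reason)
  }
  if (length(firings) == 0) {
    return(fail(NA_real_, NA_real_, 0L, "no firings"))
  }
  sta <- tryCatch(sta_template(emg, firings, fs, sta_window),
                  error = function(e) NULL)
  if (is.null(sta)) return(fail(NA_real_, NA_real_, 0L, "no usable firings"))
  r2 <- peak_ncc(as.numeric(sta), template,
                 max_shift = round(0.010 * fs))^2

  duration <- length(emg) / fs
  seg_starts <- seq(0, max(duration - seg_window, 0), by = seg_step)
  p2p <- numeric(0)
  for (s0 in seg_starts) {
    f_seg <- firings[firings >= s0 & firings < s0 + seg_window]
    if (length(f_seg) < min_firings) next
    seg_sta <- tryCatch(sta_template(emg, f_seg, fs, sta_window),
                        error = function(e) NULL)
    if (is.null(seg_sta) || attr(seg_sta, "n_used") < min_firings) next
    p2p <- c(p2p, max(seg_sta) - min(seg_sta))
  }
  if (length(p2p) < 2) {
    return(fail(r2, NA_real_, length(p2p), "insufficient segments"))
  }
  cv <- sd(p2p) / mean(p2p)
  accepted <- r2 > r2_threshold && cv < cv_threshold
  tibble::tibble(
    r_squared = r2, p2p_cv = cv, n_segments = length(p2p),
    accepted = accepted,
    reason = dplyr::case_when(
      accepted ~ NA_character_,
      r2 <= r2_threshold ~ "low STA correlation",
      TRUE ~ "unstable peak-to-peak amplitude"
    )
  )
}

#' Validate every unit of a pool
#'
#' Applies [validate_mu()] to each unit of a pool tibble against the
#' band-pass filtered EMG of the trial.
#'
#' @param bundle A `trial_bundle` (or any list with `emg`, `emg_fs` and a
#'   `units` tibble holding `id`, `firings`, `muap`).
#' @param ... Passed on to [validate_mu()].
#' @return A tibble with one row per unit: `id` plus the [validate_mu()]
#'   columns.
#' @examples
#' b <- simulate_trial_bundle(pool_config(n_units = 4), seed = 1)
#' validate_pool(b)
#' @export
validate_pool <- function(bundle, ...) {
  femg <- bandpass_emg(bundle$emg, fs = bundle$emg_fs)
  units <- bundle$units
  if ("decomposed" %in% names(units)) units <- units[units$decomposed, ]
  reports <- purrr::map(seq_len(nrow(units)), function(i) {
    validate_mu(femg, units$firings[[i]], units$muap[[i]],
                fs = bundle$emg_fs, ...)
  })
  dplyr::bind_cols(tibble::tibble(id = units$id), dplyr::bind_rows(reports))
}
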