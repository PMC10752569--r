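#' Pool-level twitch parameter bounds
#'
#' The MUDrive decoder describes the motor-unit pool by six scalars: the
#' range of peak twitch amplitudes `[p_min, p_max]` (arbitrary force units,
#' `p_min` fixed at 1), twitch rise times `[tr_min, tr_max]` (s) and twitch
#' half-relaxation times `[thr_min, thr_max]` (s). Individual units receive
#' their twitch parameters by linear rescaling of these ranges according to
#' recruitment threshold (see [rescale_twitch_params()]). Five of the six
#' scalars (`p_max`, `tr_min`, `tr_max`, `thr_min`, `thr_max`) are subject
#' to optimization within a fixed physiologic constraint box; see
#' [constraint_box()].
#'
#' @param p_max Peak twitch amplitude of the highest-threshold unit
#'   (arbitrary force units).
#' @param tr_min,tr_max Twitch rise-time range (s).
#' @param thr_min,thr_max Twitch half-relaxation-time range (s).
#' @param p_min Peak twitch amplitude of the lowest-threshold unit; fixed
#'   at 1 by convention.
#'
#' @return An object of class `pool_bounds`: a named list with the six
#'   scalars.
#' @examples
#' pool_bounds()
#' pool_bounds(p_max = 100, tr_min = 0.04)
#' @export
pool_bounds <- function(p_max = 100, tr_min = 0.03, tr_max = 0.24,
                        thr_min = 0.015, thr_max = 0.14, p_min = 1) {
  b <- list(p_min = p_min, p_max = p_max, tr_min = tr_min, tr_max = tr_max,
            thr_min = thr_min, thr_max = thr_max)
  for (nm in names(b)) {
    if (!is.numeric(b[[nm]]) || length(b[[nm]]) != 1L || !is.finite(b[[nm]])) {
      abort(sprintf("`%s` must be a finite numeric scalar.", nm))
    }
  }
  if (b$p_min >= b$p_max) abort("`p_min` must be smaller than `p_max`.")
  if (b$tr_min >= b$tr_max) abort("`tr_min` must be smaller than `tr_max`.")
  if (b$thr_min >= b$thr_max) abort("`thr_min` must be smaller than `thr_max`.")
  structure(b, class = "pool_bounds")
}

#' @export
print.pool_bounds <- function(x, ...) {
  cat("<pool_bounds>\n")
  cat(sprintf("  P:   [%g, %g] (arb. force)\n", x$p_min, x$p_max))
  cat(sprintf("  Tr:  [%g, %g] s\n", x$tr_min, x$tr_max))
  cat(sprintf("  Thr: [%g, %g] s\n", x$thr_min, x$thr_max))
  invisible(x)
}

#' Physiologic constraint box for the optimized pool parameters
#'
#' The five optimized pool parameters are constrained to conservative
#' physiologically realizable ranges (reference twitch data from the vastus
#' lateralis): peak amplitude 1.1--150 (arb. unit), minimum rise time
#' 30--110 ms, maximum rise time 150--240 ms, minimum half-relaxation time
#' 15--60 ms and maximum half-relaxation time 110--140 ms.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @examples
#' constraint_box()
#' @export
constraint_box <- function() {
  tibble::tibble(
    parameter = c("p_max", "tr_min", "tr_max", "thr_min", "thr_max"),
    lower = c(1.1, 0.030, 0.150, 0.015, 0.110),
    upper = c(150, 0.110, 0.240, 0.060, 0.140)
  )
}

#' Canonical sensitivity order of the optimized pool parameters
#'
#' Fixed ordering (most to least sensitive under low-threshold-skewed
#' pools) used for deterministic tie-breaking in [rank_parameters()] and as
#' a default ranking for refinement sweeps.
#'
#' @return Character vector of the five parameter names.
#' @examples
#' ga_parameter_order()
#' @export
ga_parameter_order <- function() {
  c("tr_min", "thr_min", "p_max", "tr_max", "thr_max")
}

#' Midpoint of the constraint box
#'
#' Returns the pool bounds with every optimized parameter fixed to the
#' midpoint of its physiologic constraint range. This is the no-optimization
#' baseline used by the refinement analysis.
#'
#' @return A [pool_bounds()] object.
#' @examples
#' midpoint_bounds()
#' @export
midpoint_bounds <- function() {
  box <- constraint_box()
  mid <- stats::setNames((box$lower + box$upper) / 2, box$parameter)
  pool_bounds(p_max = mid[["p_max"]], tr_min = mid[["tr_min"]],
              tr_max = mid[["tr_max"]], thr_min = mid[["thr_min"]],
              thr_max = mid[["thr_max"]])
}

# Replace selected parameters of a pool_bounds with new values; returns NULL
# if the combination is infeasible (min >= max) instead of erroring, so the
# optimizer can assign infinite cost.
set_bounds_params <- function(values) {
  b <- list(p_min = 1, p_max = values[["p_max"]], tr_min = values[["tr_min"]],
            tr_max = values[["tr_max"]], thr_min = values[["thr_min"]],
            thr_max = values[["thr_max"]])
  if (b$p_min >= b$p_max || b$tr_min >= b$tr_max || b$thr_min >= b$thr_max) {
    return(NULL)
  }
  structure(b, class = "pool_bounds")
}

bounds_to_vector <- function(bounds) {
  vapply(ga_parameter_order(), function(p) bounds[[p]], numeric(1))
}
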