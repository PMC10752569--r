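#' Monte-Carlo one-at-a-time sensitivity of one pool parameter
#'
#' Holds four of the five pool parameters at their optimized values and
#' perturbs the remaining one by drawing it uniformly over its physiologic
#' constraint range. Each iteration refits the MUDrive regression on the
#' training fold with the perturbed bounds and records the test-fold RMSE.
#' Iterations continue until at least `min_iterations` have run and the
#' running SD of the RMSEs has changed by less than `tol` over the final 50
#' iterations; a configurable cap guards against non-convergence.
#' Infeasible draws (minimum above maximum after combining with the fixed
#' values) are rejected and redrawn without counting.
#'
#' @param bundle A two-trapezoid `trial_bundle`; the first trapezoid is the
#'   training fold and the second the test fold.
#' @param units Retained-unit tibble (`id`, `firings`, `rt`) for the
#'   training fold; derived from the bundle if `NULL`.
#' @param optimized_bounds A [pool_bounds()], typically the GA optimum.
#' @param parameter One of `"p_max"`, `"tr_min"`, `"tr_max"`, `"thr_min"`,
#'   `"thr_max"`.
#' @param seed Integer seed.
#' @param min_iterations Minimum number of iterations (default 1000).
#' @param tol Convergence tolerance on the running SD (default 1e-4).
#' @param max_iterations Iteration cap; if reached, the result is returned
#'   with `converged = FALSE`.
#' @param config A [decoder_config()].
#' @return A one-row tibble of class `sensitivity_result`: `parameter`,
#'   `converged_sd` (Nm), `mean_rmse` (Nm), `n_iterations`, `converged`,
#'   `seed`.
#' @export
monte_carlo_sensitivity <- function(bundle, units = NULL, optimized_bounds,
                                    parameter, seed = 1,
                                    min_iterations = 1000, tol = 1e-4,
                                    max_iterations = 20000,
                                    config = decoder_config()) {
  box <- constraint_box()
  if (!parameter %in% box$parameter) {
    abort(sprintf("unknown parameter '%s'", parameter))
  }
  folds <- split_bundle(bundle)
  prep <- prepare_fold(folds[[1]], config)
  if (is.null(units)) units <- mudrive_units(prep)
  test_bundle <- folds[[2]]
  test_ref <- preprocess_torque(test_bundle$torque, fs = test_bundle$torque_fs,
                                duration = test_bundle$duration,
                                cutoff_hz = config$torque_lowpass_hz,
                                window = config$window, step = config$step)
  base <- bounds_to_vector(optimized_bounds)
  lo <- box$lower[box$parameter == parameter]
  hi <- box$upper[box$parameter == parameter]

  iter_rmse <- function(value) {
    v <- base
    v[parameter] <- value
    bounds <- set_bounds_params(v)
    if (is.null(bounds)) return(NULL)
    model <- fit_mudrive(units, bounds, prep$torque_ref, prep$duration,
                         fs = folds[[1]]$torque_fs, config = config)
    pred <- predict(model, test_bundle)
    score_prediction(pred, test_ref)
  }

  withr::with_seed(seed, {
    rmses <- numeric(0)
    sds <- numeric(0)
    converged <- FALSE
    while (length(rmses) < max_iterations) {
      r <- NULL
      while (is.null(r)) r <- iter_rmse(runif(1, lo, hi))
      rmses <- c(rmses, r)
      n <- length(rmses)
      sds[n] <- if (n > 1) sd(rmses) else 0
      if (n >= min_iterations && n > 50 &&
          abs(sds[n] - sds[n - 50]) < tol) {
        converged <- TRUE
        break
      }
    }
    structure(tibble::tibble(
      parameter = parameter,
      converged_sd = sds[length(rmses)],
      mean_rmse = mean(rmses),
      n_iterations = length(rmses),
      converged = converged,
      seed = seed
    ), class = c("sensitivity_result", "tbl_df", "tbl", "data.frame"))
  })
}

#' Sensitivity analysis of all five pool parameters
#'
#' Runs [monte_carlo_sensitivity()] for each of the five optimized pool
#' parameters and binds the results.
#'
#' @inheritParams monte_carlo_sensitivity
#' @return A 5-row sensitivity tibble.
#' @export
sensitivity_analysis <- function(bundle, units = NULL, optimized_bounds,
                                 seed = 1, ...) {
  box <- constraint_box()
  out <- purrr::map(seq_along(box$parameter), function(i) {
    monte_carlo_sensitivity(bundle, units = units,
                            optimized_bounds = optimized_bounds,
                            parameter = box$parameter[i],
                            seed = seed + i, ...)
  })
  dplyr::bind_rows(out)
}

#' Rank pool parameters by sensitivity
#'
#' Orders the five parameters by descending converged SD of RMSE (higher
#' SD means higher sensitivity). Ties are broken by a fixed canonical order
#' (`tr_min`, `thr_min`, `p_max`, `tr_max`, `thr_max`) for determinism.
#'
#' @param results A sensitivity tibble with columns `parameter` and
#'   `converged_sd` covering all five parameters.
#' @return Character vector of the 5 parameter names, most sensitive first.
#' @examples
#' res <- tibble::tibble(
#'   parameter = c("p_max", "tr_min", "tr_max", "thr_min", "thr_max"),
#'   converged_sd = c(3, 5, 2, 4, 1)
#' )
#' rank_parameters(res)
#' @export
rank_parameters <- function(results) {
  canon <- ga_parameter_order()
  if (!setequal(results$parameter, canon)) {
    abort("`results` must contain exactly the 5 pool parameters")
  }
  tie <- match(results$parameter, canon)
  results$parameter[order(-results$converged_sd, tie)]
}
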