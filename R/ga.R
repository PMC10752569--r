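#' Genetic-algorithm settings
#'
#' Hyperparameters of the real-coded genetic algorithm used to optimize the
#' MUDrive pool bounds: tournament selection, blend (BLX-alpha) crossover,
#' Gaussian mutation with SD equal to 10% of each parameter's constraint
#' range, single-individual elitism and early stopping when the best cost
#' stagnates.
#'
#' @param pop_size Population size.
#' @param n_generations Maximum number of generations.
#' @param tournament_size Tournament size for parent selection.
#' @param crossover_prob Per-pair crossover probability.
#' @param blend_alpha BLX-alpha crossover expansion factor.
#' @param mutation_prob Per-gene mutation probability.
#' @param mutation_sd_frac Mutation SD as a fraction of each parameter's
#'   constraint-box range.
#' @param elitism Number of best individuals copied unchanged.
#' @param stagnation_generations,stagnation_tol Stop early when the best
#'   cost has improved by less than `stagnation_tol` for this many
#'   consecutive generations.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 30, n_generations = 40, tournament_size = 3,
                      crossover_prob = 0.9, blend_alpha = 0.5,
                      mutation_prob = 0.25, mutation_sd_frac = 0.1,
                      elitism = 1, stagnation_generations = 10,
                      stagnation_tol = 1e-6) {
  structure(list(
    pop_size = pop_size, n_generations = n_generations,
    tournament_size = tournament_size, crossover_prob = crossover_prob,
    blend_alpha = blend_alpha, mutation_prob = mutation_prob,
    mutation_sd_frac = mutation_sd_frac, elitism = elitism,
    stagnation_generations = stagnation_generations,
    stagnation_tol = stagnation_tol
  ), class = "ga_config")
}

# cost closure: training RMSE of the MUDrive fit for a full 5-parameter
# value vector (named), Inf for infeasible combinations
mudrive_cost_fn <- function(prep, units) {
  force(prep); force(units)
  function(values) {
    bounds <- set_bounds_params(values)
    if (is.null(bounds)) return(Inf)
    model <- fit_mudrive(units, bounds, prep$torque_ref, prep$duration,
                         fs = prep$bundle$torque_fs, config = prep$config)
    model$train_rmse
  }
}

#' Optimize MUDrive pool bounds with a genetic algorithm
#'
#' Population-based search over a masked subset of the five pool
#' parameters (`p_max`, `tr_min`, `tr_max`, `thr_min`, `thr_max`) inside
#' the physiologic constraint box. The cost of a candidate is the training
#' RMSE of the MUDrive fit with those bounds (the linear regression is
#' refit for every candidate, so the cost is well defined). Parameters with
#' `mask = FALSE` stay at `fixed_values`. The constraint-box midpoint is
#' always injected into the initial population, so the returned best cost
#' never exceeds the midpoint baseline. The best candidate ever evaluated
#' is returned; runs are reproducible under a fixed seed.
#'
#' @param bundle A `trial_bundle` (training fold) or a prepared fold as
#'   produced internally by the decoders.
#' @param units Retained-unit tibble with columns `id`, `firings`, `rt`
#'   (see [fit_decoder()]); if `NULL`, derived from the bundle.
#' @param mask Logical vector of length 5 (order `p_max`, `tr_min`,
#'   `tr_max`, `thr_min`, `thr_max`) or character vector of parameter
#'   names: which parameters to optimize.
#' @param fixed_values Named numeric values for the masked-off parameters;
#'   defaults to the constraint-box midpoints.
#' @param init_values Optional list of named 5-vectors injected into the
#'   initial population (used by [refinement_sweep()] to warm-start each
#'   stage with the previous optimum, making the sweep monotone).
#' @param control A [ga_config()] with the GA hyperparameters.
#' @param seed Integer seed.
#' @param config A [decoder_config()] (used when `bundle` is a raw
#'   `trial_bundle`).
#' @return A list of class `optimization_result`: `best_bounds`,
#'   `best_cost` (Nm), `n_generations`, `n_evaluations`, `elapsed` (s),
#'   `optimized_mask`, `seed`.
#' @export
ga_optimize <- function(bundle, units = NULL, mask = rep(TRUE, 5),
                        fixed_values = NULL, init_values = NULL,
                        control = ga_config(),
                        seed = 1, config = decoder_config()) {
  t0 <- proc.time()[["elapsed"]]
  if (inherits(bundle, "trial_bundle")) {
    prep <- prepare_fold(bundle, config)
  } else {
    prep <- bundle
  }
  if (is.null(units)) units <- mudrive_units(prep)
  box <- constraint_box()
  params <- box$parameter
  if (is.character(mask)) mask <- params %in% mask
  if (length(mask) != 5) abort("`mask` must cover the 5 optimized parameters")
  names(mask) <- params
  mid <- stats::setNames((box$lower + box$upper) / 2, params)
  fixed <- mid
  if (!is.null(fixed_values)) fixed[names(fixed_values)] <- unlist(fixed_values)
  cost_fn <- mudrive_cost_fn(prep, units)
  full_values <- function(genome) {
    v <- fixed
    v[mask] <- genome
    v
  }

  result <- withr::with_seed(seed, {
    if (!any(mask)) {
      cost <- cost_fn(fixed)
      if (!is.finite(cost)) abort("degenerate training data")
      list(values = fixed, cost = cost, gens = 0L, evals = 1L)
    } else {
      lower <- box$lower[mask]
      upper <- box$upper[mask]
      d <- sum(mask)
      cfg <- control
      pop <- lapply(seq_len(cfg$pop_size), function(i) {
        runif(d, lower, upper)
      })
      pop[[1]] <- mid[mask]  # midpoint baseline always evaluated
      if (!is.null(init_values)) {
        for (j in seq_along(init_values)) {
          g <- init_values[[j]][params][mask]
          pop[[min(j + 1L, cfg$pop_size)]] <- pmin(pmax(g, lower), upper)
        }
      }
      costs <- vapply(pop, function(g) cost_fn(full_values(g)), numeric(1))
      if (all(!is.finite(costs))) abort("degenerate training data")
      best_g <- pop[[which.min(costs)]]
      best_c <- min(costs)
      evals <- cfg$pop_size
      stagnant <- 0L
      gens <- 0L
      mut_sd <- cfg$mutation_sd_frac * (upper - lower)
      for (gen in seq_len(cfg$n_generations)) {
        gens <- gen
        prev_best <- best_c
        elite_idx <- order(costs)[seq_len(cfg$elitism)]
        newpop <- pop[elite_idx]
        while (length(newpop) < cfg$pop_size) {
          p1 <- tournament(pop, costs, cfg$tournament_size)
          p2 <- tournament(pop, costs, cfg$tournament_size)
          kids <- if (runif(1) < cfg$crossover_prob) {
            blx_crossover(p1, p2, cfg$blend_alpha, lower, upper)
          } else {
            list(p1, p2)
          }
          kids <- lapply(kids, function(g) {
            mut <- runif(d) < cfg$mutation_prob
            g[mut] <- g[mut] + rnorm(sum(mut), sd = mut_sd[mut])
            pmin(pmax(g, lower), upper)
          })
          newpop <- c(newpop, kids)
        }
        pop <- newpop[seq_len(cfg$pop_size)]
        costs <- vapply(pop, function(g) cost_fn(full_values(g)), numeric(1))
        evals <- evals + cfg$pop_size
        if (min(costs) < best_c) {
          best_c <- min(costs)
          best_g <- pop[[which.min(costs)]]
        }
        if (prev_best - best_c < cfg$stagnation_tol) {
          stagnant <- stagnant + 1L
          if (stagnant >= cfg$stagnation_generations) break
        } else {
          stagnant <- 0L
        }
      }
      list(values = full_values(best_g), cost = best_c, gens = gens,
           evals = evals)
    }
  })
  structure(list(
    best_bounds = set_bounds_params(result$values),
    best_cost = result$cost,
    n_generations = result$gens,
    n_evaluations = result$evals,
    elapsed = proc.time()[["elapsed"]] - t0,
    optimized_mask = mask,
    seed = seed
  ), class = "optimization_result")
}

tournament <- function(pop, costs, k) {
  idx <- sample.int(length(pop), k)
  pop[[idx[which.min(costs[idx])]]]
}

blx_crossover <- function(p1, p2, alpha, lower, upper) {
  lo <- pmin(p1, p2)
  hi <- pmax(p1, p2)
  span <- hi - lo
  a <- lo - alpha * span
  b <- hi + alpha * span
  list(
    pmin(pmax(runif(length(p1), a, b), lower), upper),
    pmin(pmax(runif(length(p1), a, b), lower), upper)
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>\n")
  cat(sprintf("  best training RMSE: %.4g Nm after %d generation(s) (%d evaluations, %.1f s)\n",
              x$best_cost, x$n_generations, x$n_evaluations, x$elapsed))
  cat(sprintf("  optimized: %s\n",
              paste(names(x$optimized_mask)[x$optimized_mask], collapse = ", ")))
  print(x$best_bounds)
  invisible(x)
}

#' Refined optimization over the most sensitive parameters
#'
#' Masks on the `k` most sensitive parameters (per the supplied sensitivity
#' ranking), fixes the remaining `5 - k` to the midpoints of their
#' constraint-box ranges, runs [ga_optimize()] and records the elapsed
#' time. `k = 0` is the pure midpoint baseline (a single cost evaluation);
#' `k = 5` is full optimization.
#'
#' @inheritParams ga_optimize
#' @param sensitivity_rank Character vector of the 5 parameter names, most
#'   sensitive first (see [rank_parameters()]).
#' @param k Number of parameters to optimize (0--5).
#' @return An `optimization_result`.
#' @export
refine_and_time <- function(bundle, units = NULL, sensitivity_rank, k,
                            control = ga_config(), seed = 1,
                            config = decoder_config()) {
  if (length(sensitivity_rank) != 5) {
    abort("`sensitivity_rank` must name all 5 parameters")
  }
  if (k < 0 || k > 5) abort("`k` must be between 0 and 5")
  mask <- constraint_box()$parameter %in% sensitivity_rank[seq_len(k)]
  ga_optimize(bundle, units = units, mask = mask, control = control,
              seed = seed, config = config)
}

#' Warm-started refinement sweep over the number of optimized parameters
#'
#' Runs the refinement analysis for `k = 0, 1, ..., 5` optimized
#' parameters (most sensitive first). Each stage injects the previous
#' stage's optimum into its initial population (the newly freed parameter
#' sat at its midpoint there, so the candidate is feasible), which makes
#' the best cost nonincreasing in `k` by construction.
#'
#' @inheritParams refine_and_time
#' @param ks Integer vector of `k` values (default `0:5`).
#' @return A tibble with one row per `k`: `k`, `best_cost` (Nm),
#'   `elapsed` (s), `n_evaluations`, and a list-column `bounds`.
#' @export
refinement_sweep <- function(bundle, units = NULL, sensitivity_rank,
                             ks = 0:5, control = ga_config(), seed = 1,
                             config = decoder_config()) {
  if (inherits(bundle, "trial_bundle")) {
    bundle <- prepare_fold(bundle, config)
  }
  if (is.null(units)) units <- mudrive_units(bundle)
  prev <- NULL
  rows <- list()
  for (k in ks) {
    mask <- constraint_box()$parameter %in% sensitivity_rank[seq_len(k)]
    res <- ga_optimize(bundle, units = units, mask = mask,
                       init_values = prev, control = control,
                       seed = seed + k, config = config)
    prev <- list(bounds_to_vector(res$best_bounds))
    rows[[length(rows) + 1]] <- tibble::tibble(
      k = k, best_cost = res$best_cost, elapsed = res$elapsed,
      n_evaluations = res$n_evaluations, bounds = list(res$best_bounds)
    )
  }
  dplyr::bind_rows(rows)
}
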