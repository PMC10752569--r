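#' Root-mean-square error between two index-aligned feature series
#'
#' @param estimate,reference Feature series tibbles on the same grid and of
#'   equal length.
#' @return RMSE in the series units (Nm for torque).
#' @examples
#' a <- tibble::tibble(time = 1:5 / 10, value = 1:5)
#' b <- tibble::tibble(time = 1:5 / 10, value = 1:5 + 1)
#' rmse(a, b)
#' @export
rmse <- function(estimate, reference) {
  if (nrow(estimate) != nrow(reference)) {
    abort("`estimate` and `reference` must have equal length")
  }
  sqrt(mean((estimate$value - reference$value)^2))
}

# inner-join a prediction with a reference on the (rounded) time grid and
# return the RMSE over the overlap
score_prediction <- function(pred, reference) {
  key_p <- round(pred$time, 6)
  key_r <- round(reference$time, 6)
  common <- intersect(key_p, key_r)
  if (length(common) == 0) abort("prediction and reference do not overlap")
  rmse(pred[match(common, key_p), ], reference[match(common, key_r), ])
}

#' Split a two-trapezoid trial into its cross-validation folds
#'
#' Splits the bundle at the midpoint of the rest between the two
#' trapezoids, returning a list of two single-trapezoid bundles with times
#' re-referenced to each fold's start.
#'
#' @param bundle A `trial_bundle` with exactly two trapezoids.
#' @return List of two `trial_bundle`s.
#' @export
split_bundle <- function(bundle) {
  traps <- attr(bundle$profile, "trapezoids")
  if (is.null(traps) || nrow(traps) != 2) {
    abort("two-fold cross-validation requires a bundle with exactly 2 trapezoids")
  }
  t_split <- (traps$end[1] + traps$start[2]) / 2
  list(
    crop_bundle(bundle, 0, t_split),
    crop_bundle(bundle, t_split, bundle$duration)
  )
}

#' Two-fold cross-validated decoding error for one trial
#'
#' Splits a two-trapezoid trial at the midpoint of the inter-trapezoid
#' rest, trains the decoder (including any GA optimization for MUDrive) on
#' one fold, predicts the other and computes the test RMSE on the 10 Hz
#' grid, then swaps the folds. The alignment lag is estimated on the
#' training fold and reused on the test fold; no test data enters
#' training.
#'
#' @param bundle A two-trapezoid `trial_bundle`.
#' @param method One of `"aEMG"`, `"ND"`, `"MUDrive"`.
#' @param config A [decoder_config()].
#' @param seed Integer seed (GA randomness for MUDrive).
#' @param ... Passed on to [fit_decoder()] (e.g. `optimize = FALSE`,
#'   `bounds = ...` for the midpoint-baseline MUDrive).
#' @return A one-row tibble: `method`, `fold_rmse_1`, `fold_rmse_2`,
#'   `mean_rmse` (Nm).
#' @export
two_fold_cv <- function(bundle, method, config = decoder_config(), seed = 1,
                        ...) {
  folds <- split_bundle(bundle)
  fold_rmse <- vapply(1:2, function(i) {
    train <- folds[[i]]
    test <- folds[[3 - i]]
    model <- fit_decoder(train, method, config = config, seed = seed + i, ...)
    pred <- predict(model, test)
    test_ref <- preprocess_torque(test$torque, fs = test$torque_fs,
                                  duration = test$duration,
                                  cutoff_hz = config$torque_lowpass_hz,
                                  window = config$window,
                                  step = config$step)
    score_prediction(pred, test_ref)
  }, numeric(1))
  tibble::tibble(method = method, fold_rmse_1 = fold_rmse[1],
                 fold_rmse_2 = fold_rmse[2], mean_rmse = mean(fold_rmse))
}

#' Paired post-hoc comparisons of decoder performance
#'
#' Student's paired t-tests between every pair of methods on per-subject
#' mean RMSE, with Bonferroni correction (raw p multiplied by the number of
#' pairs, capped at 1) and a paired Cohen's d (mean difference divided by
#' the SD of the differences). When the SD of the differences is zero the
#' comparison is degenerate: identical columns give t = 0 and p = 1; a
#' constant nonzero shift gives infinite t, p = 0 and a degeneracy flag.
#'
#' @param results A tibble with columns `subject`, `method` and `rmse`
#'   (one row per subject and method, e.g. per-subject means).
#' @return A tibble of class `cohort_stats` with one row per method pair:
#'   `pair`, `mean_diff`, `t_statistic`, `df`, `p_value`, `p_adjusted`,
#'   `cohens_d`, `degenerate`.
#' @export
paired_posthoc <- function(results) {
  # canonical, locale-independent method order for stable pair labels
  canon <- c("aEMG", "ND", "MUDrive")
  methods <- unique(results$method)
  methods <- c(intersect(canon, methods), sort(setdiff(methods, canon)))
  subjects <- sort(unique(results$subject))
  if (length(subjects) < 3) abort("need at least 3 subjects for paired tests")
  wide <- tidyr::pivot_wider(results[, c("subject", "method", "rmse")],
                             names_from = "method", values_from = "rmse")
  for (m in methods) {
    if (any(is.na(wide[[m]]))) {
      missing_subj <- wide$subject[is.na(wide[[m]])][1]
      abort(sprintf("subject '%s' is missing method '%s'", missing_subj, m))
    }
  }
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  rows <- purrr::map(pairs, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    n <- length(d)
    sd_d <- sd(d)
    if (sd_d == 0) {
      if (all(d == 0)) {
        t_stat <- 0; p <- 1; dg <- FALSE; cd <- 0
      } else {
        t_stat <- sign(mean(d)) * Inf; p <- 0; dg <- TRUE; cd <- sign(mean(d)) * Inf
      }
    } else {
      tt <- t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
      dg <- FALSE
      cd <- mean(d) / sd_d
    }
    tibble::tibble(
      pair = paste(pr, collapse = "-"), mean_diff = mean(d),
      t_statistic = t_stat, df = n - 1L, p_value = p,
      p_adjusted = min(1, p * n_pairs), cohens_d = cd, degenerate = dg
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("cohort_stats", "tbl_df", "tbl", "data.frame"))
}

#' Cohort configuration for the virtual-subject study
#'
#' Defines a cohort of virtual subjects, each with its own motor-unit pool
#' realization, performing two-trapezoid trials at each target level.
#' The number of decomposed units varies per subject (drawn uniformly from
#' `n_decomposed_range`), emulating the between-subject spread of
#' decomposition yields.
#'
#' @param n_subjects Number of virtual subjects.
#' @param target_levels Target plateau levels (%MVC).
#' @param n_decomposed_range Range of decomposed-unit counts sampled per
#'   subject (the observed yield of surface decomposition varies widely
#'   between subjects).
#' @param base_config A [pool_config()] template; `n_decomposed` is
#'   overridden per subject.
#' @param decoder A [decoder_config()]; its `ga` settings govern the
#'   per-fold MUDrive optimization.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8, target_levels = c(20, 35),
                          n_decomposed_range = c(15, 35),
                          base_config = pool_config(),
                          decoder = decoder_config(ga = ga_config(
                            pop_size = 15, n_generations = 20))) {
  structure(list(
    n_subjects = n_subjects, target_levels = target_levels,
    n_decomposed_range = n_decomposed_range, base_config = base_config,
    decoder = decoder
  ), class = "cohort_config")
}

#' Run the virtual-subject cohort evaluation
#'
#' Generates `n_subjects` virtual subjects (distinct pool realizations and
#' seeds), simulates one two-trapezoid trial per subject and target level,
#' evaluates all three decoders by two-fold cross-validation and aggregates
#' the results: per-trial fold RMSEs, per-condition summaries and paired
#' post-hoc statistics on per-subject mean RMSE.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @param methods Decoding methods to evaluate.
#' @param mudrive_optimize Logical; run the GA when fitting MUDrive
#'   (default `TRUE`). `FALSE` gives the midpoint-baseline MUDrive.
#' @return A list of class `cohort_report`: `results` (long tibble:
#'   subject, target_mvc, method, fold, rmse), `summary` (mean and SE of
#'   RMSE by method and level), `subject_means`, `stats` (paired post-hoc
#'   tibble, `NULL` with a warning for fewer than 3 subjects), `seed`.
#' @export
run_cohort <- function(config = cohort_config(), seed = 1,
                       methods = c("aEMG", "ND", "MUDrive"),
                       mudrive_optimize = TRUE) {
  subj_setup <- withr::with_seed(seed, {
    lapply(seq_len(config$n_subjects), function(s) {
      list(
        n_decomposed = sample(seq(config$n_decomposed_range[1],
                                  config$n_decomposed_range[2]), 1),
        seed = sample.int(1e6, 1)
      )
    })
  })
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    pcfg <- config$base_config
    pcfg$n_decomposed <- subj_setup[[s]]$n_decomposed
    for (lvl in config$target_levels) {
      bundle <- simulate_trial_bundle(pcfg, target_mvc = lvl,
                                      n_trapezoids = 2,
                                      seed = subj_setup[[s]]$seed + round(lvl))
      for (m in methods) {
        cv <- if (m == "MUDrive") {
          two_fold_cv(bundle, m, config = config$decoder,
                      seed = subj_setup[[s]]$seed,
                      optimize = mudrive_optimize)
        } else {
          two_fold_cv(bundle, m, config = config$decoder,
                      seed = subj_setup[[s]]$seed)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = sprintf("S%02d", s), target_mvc = lvl, method = m,
          fold = 1:2, rmse = c(cv$fold_rmse_1, cv$fold_rmse_2)
        )
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$method, .data$target_mvc) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     se_rmse = sd(.data$rmse) / sqrt(dplyr::n()),
                     .groups = "drop")
  subject_means <- results |>
    dplyr::group_by(.data$subject, .data$method) |>
    dplyr::summarise(rmse = mean(.data$rmse), .groups = "drop")
  stats <- if (config$n_subjects >= 3) {
    paired_posthoc(subject_means)
  } else {
    warn("fewer than 3 subjects: paired statistics suppressed")
    NULL
  }
  structure(list(results = results, summary = summary,
                 subject_means = subject_means, stats = stats, seed = seed),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  %d subject(s), %d trial-fold RMSE value(s)\n",
              length(unique(x$results$subject)), nrow(x$results)))
  print(x$summary)
  if (!is.null(x$stats)) {
    cat("Paired post-hoc comparisons (Bonferroni-adjusted):\n")
    print(tibble::as_tibble(x$stats))
  }
  invisible(x)
}
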