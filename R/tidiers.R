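#' Tidy a fitted decoder model
#'
#' @param x A `decoder_model`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`).
#' @export
tidy.decoder_model <- function(x, ...) {
  terms <- if (length(x$unit_ids) > 0 && x$method == "ND") {
    paste0("FR_", x$unit_ids)
  } else if (x$method == "MUDrive") {
    "mudrive"
  } else {
    "aemg"
  }
  tibble::tibble(
    term = c("(Intercept)", terms),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row summary of a fitted decoder model
#'
#' @param x A `decoder_model`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_units`, `lag`, `train_rmse`,
#'   `r_squared`.
#' @export
glance.decoder_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_units = length(x$unit_ids), lag = x$lag,
    train_rmse = x$train_rmse, r_squared = x$r_squared
  )
}

#' Tidy a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return The long per-trial results tibble (`subject`, `target_mvc`,
#'   `method`, `fold`, `rmse`).
#' @export
tidy.cohort_report <- function(x, ...) x$results

#' One-row summary of a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return A one-row tibble: subject count, per-method mean RMSE and the
#'   smallest Bonferroni-adjusted p-value.
#' @export
glance.cohort_report <- function(x, ...) {
  by_method <- x$results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(m = mean(.data$rmse), .groups = "drop")
  out <- tibble::tibble(
    n_subjects = length(unique(x$results$subject)),
    min_p_adjusted = if (!is.null(x$stats)) min(x$stats$p_adjusted) else NA_real_
  )
  for (i in seq_len(nrow(by_method))) {
    out[[paste0("mean_rmse_", by_method$method[i])]] <- by_method$m[i]
  }
  out
}

#' Plot a simulated trial bundle
#'
#' Shows the excitation profile and the synthesized torque trace of a
#' trial.
#'
#' @param object A `trial_bundle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_bundle <- function(object, ...) {
  tq <- tibble::tibble(
    time = (seq_along(object$torque) - 1) / object$torque_fs,
    value = object$torque, panel = "torque (Nm)"
  )
  ex <- tibble::tibble(time = object$profile$time,
                       value = object$profile$excitation,
                       panel = "excitation (%MVC)")
  ggplot2::ggplot(dplyr::bind_rows(ex, tq),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cohort decoding performance
#'
#' Per-method RMSE distribution across subjects and target levels, the
#' cohort-level analogue of a method-comparison figure.
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_report <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$method, y = .data$rmse)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(colour = factor(.data$target_mvc)),
                         width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "test RMSE (Nm)",
                  colour = "target (%MVC)") +
    ggplot2::theme_minimal()
}

#' Plot a decoder prediction against the torque reference
#'
#' @param prediction Feature series from [predict.decoder_model()].
#' @param reference Torque reference feature series.
#' @return A ggplot object.
#' @export
plot_prediction <- function(prediction, reference) {
  df <- dplyr::bind_rows(
    dplyr::mutate(prediction, series = "estimate"),
    dplyr::mutate(reference, series = "torque")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "torque (Nm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot parameter sensitivities
#'
#' Bar chart of the converged SD of RMSE per pool parameter, ordered most
#' to least sensitive.
#'
#' @param results A sensitivity tibble (see [sensitivity_analysis()]).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(results) {
  ord <- rank_parameters(results)
  results$parameter <- factor(results$parameter, levels = ord)
  ggplot2::ggplot(results, ggplot2::aes(x = .data$parameter,
                                        y = .data$converged_sd)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "SD of test RMSE (Nm)") +
    ggplot2::theme_minimal()
}
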