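# ggplot2 displays for the main result types.

#' Plot an estimation result
#'
#' Shows the fitted enhancement curve on the ISI grid, the observation log,
#' and the estimated window as a shaded band.
#'
#' @param object An [estimate_isi_window()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isiw_estimate <- function(object, ...) {
  w <- object$window
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$isi, y = .data$mep)) +
    ggplot2::annotate("rect", xmin = w$lower, xmax = w$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = object$observations, alpha = 0.6) +
    ggplot2::labs(
      x = "ISI (ms)", y = "MEP (mV)",
      title = sprintf("%s estimate: window [%.1f, %.1f] ms, %d observations%s",
                      object$method, w$lower, w$upper, object$n_observations,
                      if (object$converged) "" else " (not converged)")) +
    ggplot2::theme_minimal()
}

#' Plot an incremental sweep
#'
#' Mean MEP per grid ISI with the extracted ground-truth window shaded and
#' the baseline marked.
#'
#' @param object An [incremental_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isiw_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$isi, y = .data$mean_mep))
  if (!object$empty) {
    p <- p + ggplot2::annotate("rect", xmin = object$window$lower,
                               xmax = object$window$upper,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "darkgreen")
  }
  p +
    ggplot2::geom_hline(yintercept = object$subject$baseline_mep,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "ISI (ms)", y = "mean MEP (mV)",
                  title = "Incremental sweep profile") +
    ggplot2::theme_minimal()
}

#' Plot a benchmark report
#'
#' Bar panels of mean F1 and mean observation count per method / `n_ini` /
#' accelerometer-mode cell.
#'
#' @param object A [run_benchmark()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isiw_benchmark <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object)) |>
    dplyr::filter(.data$available) |>
    dplyr::mutate(
      cell = paste0(.data$method,
                    ifelse(is.na(.data$n_ini), "", paste0("/", .data$n_ini))),
      mode = ifelse(.data$accelerometer, "with ACC", "without ACC")) |>
    tidyr::pivot_longer(c("mean_f1", "mean_n_obs"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         mean_f1 = "mean F1",
                                         mean_n_obs = "mean observations"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$value,
                                  fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "method / n_ini", y = NULL, fill = NULL,
                  title = "Estimator benchmark") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
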