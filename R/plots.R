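#' Plot the fitted voltage densities of one (nucleotide, zone) stratum
#'
#' Draws the class-conditional Gaussian voltage densities, one curve per
#' homopolymer length — the standard way to inspect how quickly the signal
#' classes blur as length grows.
#'
#' @param object A [signal_priors()] object.
#' @param nucleotide,zone The stratum to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_priors <- function(object, nucleotide = "A", zone = 1L, ...) {
  cells <- dplyr::filter(object$cells, .data$nucleotide == !!nucleotide,
                         .data$zone == !!zone)
  grid <- cells |>
    dplyr::reframe(
      voltage = seq(.data$mean - 4 * .data$stdev, .data$mean + 4 * .data$stdev,
                    length.out = 200),
      .by = "length"
    ) |>
    dplyr::left_join(cells, by = "length") |>
    dplyr::mutate(density = dnorm(.data$voltage, .data$mean, .data$stdev))
  ggplot2::ggplot(grid, ggplot2::aes(.data$voltage, .data$density,
                                     colour = factor(.data$length))) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "voltage (incorporation units)", y = "density",
      colour = "length",
      title = sprintf("Voltage signal classes: %s, zone %d", nucleotide, zone)
    ) +
    ggplot2::theme_minimal()
}

weight_curve_plot <- function(curve, y, best_weight, ylab) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$weight, {{ y }})) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = best_weight, linetype = "dashed") +
    ggplot2::labs(x = "weight W", y = ylab,
                  subtitle = sprintf("selected W = %.2f", best_weight)) +
    ggplot2::theme_minimal()
}

#' Plot a weight optimization or sweep curve
#'
#' Identification error as a function of the integrated-model weight W, with
#' the selected weight marked. W = 0 is the reference-only caller, W = 1 the
#' Bayesian-only caller.
#'
#' @param object A `weight_fit` (from [optimize_weight()]) or `weight_sweep`
#'   object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weight_fit <- function(object, ...) {
  weight_curve_plot(object$curve, .data$cv_error, object$best_weight,
                    "cross-validated error rate")
}

#' @rdname autoplot.weight_fit
#' @export
autoplot.weight_sweep <- function(object, ...) {
  weight_curve_plot(object$curve, .data$errors, object$best_weight,
                    "identification errors (full set)")
}

#' Plot an evaluation as per-cell method comparison
#'
#' Error percentage per (nucleotide, zone) cell, dodged by calling method.
#'
#' @param object An `hp_evaluation` from [evaluate_calls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_evaluation <- function(object, ...) {
  ggplot2::ggplot(
    object$by_cell,
    ggplot2::aes(factor(.data$zone), .data$error_percent, fill = .data$method)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~nucleotide) +
    ggplot2::labs(x = "read-position zone", y = "identification error (%)",
                  fill = "method") +
    ggplot2::theme_minimal()
}
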