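#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted mutational-robustness logistic curve
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot: per-distance fractions and the fitted curve, with
#'   the LD50 marked.
#' @exportS3Method ggplot2::autoplot
autoplot.logistic_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  xs <- seq(min(object$data$n_muts), max(object$data$n_muts),
            length.out = 100)
  curve <- tibble::tibble(
    x = xs, y = object$L / (1 + exp(-object$k * (xs - object$x0))))
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$n_muts,
                                    y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       color = "firebrick") +
    ggplot2::labs(x = "amino-acid substitutions",
                  y = "fraction of genotypes",
                  title = object$mode %||% "logistic fit") +
    ggplot2::theme_minimal()
  if (!is.na(object$ld50)) {
    p <- p + ggplot2::geom_vline(xintercept = object$ld50,
                                 linetype = "dashed")
  }
  p
}

#' Plot the training history of a fitness network
#'
#' @param object A `fitnet`.
#' @param ... Unused.
#' @return A ggplot of train/validation MSE per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.fitnet <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "set", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "MSE (log10 fluorescence)",
                  title = paste("fitnet:", object$arch$name)) +
    ggplot2::theme_minimal()
}

#' Plot a genetic-algorithm trajectory
#'
#' @param object A `ga_run`.
#' @param ... Unused.
#' @return A ggplot of the population median and best prediction per
#'   generation.
#' @exportS3Method ggplot2::autoplot
autoplot.ga_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("median_pred", "best_pred"),
                              names_to = "stat", values_to = "pred")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$pred,
                                     color = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "predicted log10 fluorescence") +
    ggplot2::theme_minimal()
}

#' Fluorescence distribution of a genotype dataset
#'
#' The characteristic bimodal histogram: a dark mode and a near-wildtype
#' mode.
#'
#' @param dataset Tibble with `fluorescence`.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_fluorescence_distribution <- function(dataset, bins = 60) {
  ggplot2::ggplot(dataset, ggplot2::aes(x = .data$fluorescence)) +
    ggplot2::geom_histogram(bins = bins, fill = "seagreen") +
    ggplot2::labs(x = "log10 fluorescence", y = "genotypes") +
    ggplot2::theme_minimal()
}

#' Plot a median-fluorescence peak profile
#'
#' @param profile A [peak_profile()] tibble (optionally several,
#'   row-bound with an `origin` column).
#' @return A ggplot of median fluorescence vs distance.
#' @export
plot_peak_profile <- function(profile) {
  aes <- if ("origin" %in% names(profile)) {
    ggplot2::aes(x = .data$distance, y = .data$median_f,
                 color = .data$origin)
  } else {
    ggplot2::aes(x = .data$distance, y = .data$median_f)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "amino-acid substitutions",
                  y = "median log10 fluorescence") +
    ggplot2::theme_minimal()
}

#' Plot the additive-fraction curve
#'
#' @param curve An [additive_fraction_curve()] tibble.
#' @return A ggplot; the dashed line at 1 is the no-epistasis
#'   expectation.
#' @export
plot_additive_fraction <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_muts,
                                      y = .data$fraction)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "amino-acid substitutions",
                  y = "observed / expected functional") +
    ggplot2::theme_minimal()
}

#' Plot a learned potential-to-fluorescence transform
#'
#' @param curve A [transform_curve()] tibble.
#' @return A ggplot.
#' @export
plot_transform_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$potential,
                                      y = .data$fluorescence)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fitness potential",
                  y = "predicted log10 fluorescence") +
    ggplot2::theme_minimal()
}
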