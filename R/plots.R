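#' Plot the flux distribution of an RBA solution
#'
#' @param object an `rba_solution`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rba_solution <- function(object, ...) {
  td <- tidy(object) |> dplyr::filter(.data$flux != 0)
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$reaction, abs(.data$flux)), y = .data$flux)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flux (mmol gDCW⁻¹ hr⁻¹)",
                  title = sprintf("condition %s, µ = %.3f hr⁻¹",
                                  object$condition, object$mu)) +
    ggplot2::theme_minimal()
}

#' Plot a forced-flux sweep
#'
#' Growth rate, biomass yield and net CO2 emission against the forced flux,
#' one panel each.
#'
#' @param sweep tibble with columns `forced`, `mu`, `yield`, `co2_emission`.
#' @return a ggplot.
#' @export
plot_forced_flux <- function(sweep) {
  long <- sweep |>
    tidyr::pivot_longer(c("mu", "yield", "co2_emission"),
                        names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$forced, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "forced flux (mmol gDCW⁻¹ hr⁻¹)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the insertion-index distribution with the fitted mixture
#'
#' Histogram of insertion indices overlaid with the two fitted gamma
#' components and the essentiality thresholds.
#'
#' @param calls [classify_essentiality()] output (carries the fit and
#'   thresholds as attributes).
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_insertion_index <- function(calls, bins = 60) {
  fit <- attr(calls, "fit"); thr <- attr(calls, "thresholds")
  x <- calls$ii[!is.na(calls$ii)]
  grid <- seq(1e-4, max(x) * 1.05, length.out = 400)
  dens <- dplyr::bind_rows(
    tibble::tibble(ii = grid, component = "essential",
                   density = fit$weight_low *
                     dgamma(grid, fit$shape["low"], fit$rate["low"])),
    tibble::tibble(ii = grid, component = "non-essential",
                   density = (1 - fit$weight_low) *
                     dgamma(grid, fit$shape["high"], fit$rate["high"])))
  ggplot2::ggplot(calls, ggplot2::aes(.data$ii)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", color = "grey50") +
    ggplot2::geom_line(data = dens, ggplot2::aes(
      y = .data$density, color = .data$component)) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "insertion index", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot mean enzyme utilization by category
#'
#' @param categories [categorize_utilization()] output.
#' @return a ggplot.
#' @export
plot_utilization <- function(categories) {
  ggplot2::ggplot(categories, ggplot2::aes(
    .data$mean_utilization, fill = .data$category)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(33, 66), linetype = "dashed") +
    ggplot2::labs(x = "mean utilization (%)", y = "enzymes") +
    ggplot2::theme_minimal()
}

#' Plot gene fitness scores
#'
#' Fitness against gene rank per sample, with the significance band.
#'
#' @param scores [significance_call()] output.
#' @param threshold significance threshold drawn as dashed lines.
#' @return a ggplot.
#' @export
plot_fitness <- function(scores, threshold = 3) {
  ggplot2::ggplot(scores, ggplot2::aes(
    x = rank(.data$fitness), y = .data$fitness,
    color = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~.data$sample) +
    ggplot2::labs(x = "gene rank", y = expression(log[2]~fitness~F)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
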