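#' Plot an h-value distribution with optional thresholds
#'
#' @param h_table A data frame with an `h` column (e.g. [add_h_values()]
#'   output), typically filtered to one frame.
#' @param thresholds Optional `(low, high)` homoplasmy cutoffs drawn as
#'   dashed lines.
#' @param bins Histogram bins (default 40).
#' @return A ggplot object.
#' @export
plot_h_distribution <- function(h_table, thresholds = NULL, bins = 40) {
  stopifnot("h" %in% names(h_table))
  p <- ggplot2::ggplot(h_table[!is.na(h_table$h), ],
                       ggplot2::aes(x = .data$h)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", color = "white") +
    ggplot2::geom_density(color = "black") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "heteroplasmy value h", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(thresholds),
                                 linetype = "dashed", color = "grey30")
  }
  p
}

#' Plot homoplasmy-fraction time courses
#'
#' @param curves A data frame with `time_h`, `fraction` and optionally a
#'   grouping column (e.g. one curve per parameter pair).
#' @param group Optional name of the grouping column.
#' @return A ggplot object.
#' @export
plot_homoplasmy_curves <- function(curves, group = NULL) {
  aes <- if (is.null(group)) {
    ggplot2::aes(x = .data$time_h, y = .data$fraction)
  } else {
    ggplot2::aes(x = .data$time_h, y = .data$fraction,
                 color = factor(.data[[group]]), group = .data[[group]])
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        color = "grey60") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (h)", y = "fraction homoplasmic",
                  color = group) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a grid-search SSE surface
#'
#' @param object A [grid_search()] fit.
#' @param ... Unused.
#' @return A ggplot object; the best pair is marked.
#' @method autoplot grid_fit
#' @export
autoplot.grid_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$ndau, y = .data$nspl,
                               fill = .data$sse)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = tibble::tibble(ndau = object$best_ndau,
                            nspl = object$best_nspl),
      ggplot2::aes(x = .data$ndau, y = .data$nspl),
      inherit.aes = FALSE, shape = 4, size = 3, stroke = 1.5,
      color = "white") +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "ndau (copies to daughter)",
                  y = "nspl (fragments per shuffle)",
                  fill = "SSE") +
    ggplot2::theme_minimal()
}

#' Gaussian mixture fit over the data density
#'
#' @param object A [fit_gaussian_mixture()] fit.
#' @param h Optional raw h values to underlay as a histogram.
#' @param ... Unused.
#' @return A ggplot object with the three component curves.
#' @method autoplot gmm_fit
#' @export
autoplot.gmm_fit <- function(object, h = NULL, ...) {
  grid <- seq(0, 1, length.out = 400)
  comp <- object$components
  curves <- purrr::pmap_dfr(comp, function(component, weight, mean, sd) {
    tibble::tibble(component = factor(component), h = grid,
                   density = weight * stats::dnorm(grid, mean, sd))
  })
  p <- ggplot2::ggplot()
  if (!is.null(h)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(h = h[!is.na(h)]),
      ggplot2::aes(x = .data$h, y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey85", color = "white")
  }
  p + ggplot2::geom_line(
    data = curves,
    ggplot2::aes(x = .data$h, y = .data$density,
                 color = .data$component)) +
    ggplot2::labs(x = "heteroplasmy value h", y = "density") +
    ggplot2::theme_minimal()
}

#' Exponential decay fit over the measured series
#'
#' @param object A [fit_decay()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "normalized intensity (a.u.)") +
    ggplot2::theme_minimal()
}
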