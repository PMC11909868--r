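# ggplot2 displays for each result type.

#' Plot a cost-effectiveness acceptability curve
#'
#' One curve per strategy: probability of attaining the maximum net
#' monetary benefit across PSA draws, as a function of willingness-to-pay.
#'
#' @param object A `cea_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' psa <- run_psa(default_registry(), n = 200, seed = 1)
#' ggplot2::autoplot(ceac(psa))
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$wtp, y = .data$probability,
                 colour = .data$strategy)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(labels = function(x) x / 1000) +
    ggplot2::labs(
      x = "Willingness-to-pay ($1,000 per QALY)",
      y = "Probability cost-effective",
      colour = "Strategy"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane and efficiency frontier
#'
#' @param object A `cea_frontier` tibble from [icer_frontier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_frontier <- function(object, ...) {
  frontier <- object[object$status == "on_frontier", ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = frontier, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "QALYs", y = "Cost ($)", shape = "Status") +
    ggplot2::theme_minimal()
}

#' Plot a one-way sensitivity sweep
#'
#' @param object A `cea_sweep` tibble from [one_way_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_sweep <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$value, y = .data$result, colour = .data$strategy)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = unique(object$param), y = unique(object$metric),
      colour = "Strategy"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the metric values at each parameter's
#' sensitivity bounds, for one strategy at a time.
#'
#' @param object A `cea_tornado` tibble from [tornado()].
#' @param strategy Which strategy's bars to draw (default: first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_tornado <- function(object, strategy = NULL, ...) {
  if (is.null(strategy)) strategy <- object$strategy[1]
  dat <- object[object$strategy == strategy, ]
  dat$param <- stats::reorder(dat$param, dat$span)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(y = .data$param, xmin = pmin(.data$at_low, .data$at_high),
                 xmax = pmax(.data$at_low, .data$at_high))
  ) +
    ggplot2::geom_linerange(linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "Metric value", y = NULL, title = strategy) +
    ggplot2::theme_minimal()
}
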