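#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cost-effectiveness acceptability curves
#'
#' One curve per strategy: the probability of positive net monetary benefit
#' against the Referent as a function of the willingness-to-pay threshold.
#'
#' @param object an `ls_ceac` (from [ceac()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ls_ceac
#' @export
autoplot.ls_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$threshold, y = .data$probability, colour = .data$strategy
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (USD per life-year gained)",
      y = "Probability cost-effective vs Referent",
      colour = NULL,
      title = "Cost-effectiveness acceptability curves"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ls_ceac
#' @param x an `ls_ceac`.
#' @export
plot_ceac <- function(x, ...) autoplot(x, ...)

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the ICER obtained at each parameter's low and
#' high bound, ordered by influence, with the base-case ICER as a reference
#' line.
#'
#' @param object an `ls_tornado` (from [tornado()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ls_tornado
#' @export
autoplot.ls_tornado <- function(object, ...) {
  base <- attr(object, "icer_base")
  df <- dplyr::mutate(object,
                      parameter = factor(.data$parameter,
                                         levels = rev(.data$parameter)),
                      lo = pmin(.data$icer_low, .data$icer_high),
                      hi = pmax(.data$icer_low, .data$icer_high))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi, yend = .data$parameter),
      linewidth = 4, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(
      x = "ICER vs Referent (USD per life-year gained)", y = NULL,
      title = sprintf("One-way sensitivity analysis (%s)",
                      attr(object, "strategy"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ls_tornado
#' @param x an `ls_tornado`.
#' @export
plot_tornado <- function(x, ...) autoplot(x, ...)
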