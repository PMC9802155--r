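#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Contour plot of a fitted-surface slice
#'
#' Filled-contour rendering of a [surface_slice()], with the slice
#' maximum marked. The two free factors are on the axes (coded scale);
#' the remaining factors are clamped at the levels recorded in the
#' slice.
#'
#' @param object A `quad_slice`.
#' @param bins Number of contour bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' fit <- fit_quadratic(fyn22_runs(), fyn22_factors())
#' autoplot(surface_slice(fit, c("A", "B")))
#' @method autoplot quad_slice
#' @export
autoplot.quad_slice <- function(object, bins = 12, ...) {
  free <- attr(object, "free")
  fixed <- attr(object, "fixed")
  mx <- attr(object, "slice_max")
  sub <- if (length(fixed) > 0) {
    paste("held:", paste(names(fixed), "=", fixed, collapse = ", "))
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[free[1]]],
                                       y = .data[[free[2]]],
                                       z = .data$predicted)) +
    ggplot2::geom_contour_filled(bins = bins) +
    ggplot2::geom_point(data = mx, ggplot2::aes(x = .data[[free[1]]],
                                                y = .data[[free[2]]]),
                        inherit.aes = FALSE, shape = 3, size = 3) +
    ggplot2::labs(x = paste0(free[1], " (coded)"),
                  y = paste0(free[2], " (coded)"),
                  fill = "predicted", subtitle = sub) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-term influence from the ANOVA
#'
#' Plots the partial F statistic of every model term, ordered by
#' influence, with significant terms (at the table's alpha)
#' highlighted. The conventional reading of "which factor matters
#' most" in a response-surface ANOVA.
#'
#' @param anova A `quad_anova` from [anova_quad()].
#' @return A ggplot object.
#' @examples
#' fit <- fit_quadratic(fyn22_runs(), fyn22_factors())
#' plot_effects(anova_quad(fit))
#' @export
plot_effects <- function(anova) {
  stopifnot(inherits(anova, "quad_anova"))
  terms <- anova[!anova$source %in%
                   c("Model", "Residual", "Lack of fit", "Pure error",
                     "Corrected total"), ]
  terms <- dplyr::arrange(terms, .data$statistic)
  terms$source <- factor(terms$source, levels = terms$source)
  ggplot2::ggplot(terms, ggplot2::aes(x = .data$statistic, y = .data$source,
                                      fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "partial F", y = NULL, fill = paste0("p < ", attr(anova, "alpha"))) +
    ggplot2::theme_minimal()
}
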