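#' Plot a segment profile (shortest diameter against distance along the vessel)
#'
#' The classic stenosis graph: shortest cross-section diameter on the vertical
#' axis, distance from the vessel start on the horizontal, with
#' maximum-ineligible positions (too close to the aorta or a bifurcation)
#' de-emphasized.
#'
#' @param object a `segment_profile`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.segment_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[df$valid, ],
                  ggplot2::aes(x = arc_mm, y = diameter_mm,
                               colour = max_eligible)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "grey70"),
                                 name = "max-eligible") +
    ggplot2::labs(x = "distance from vessel start (mm)",
                  y = "shortest cross-section diameter (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.segment_profile
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUROC %.2f (%.2f-%.2f)", object$auc,
                                  object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of paired measurements
#'
#' Differences against pair means with the mean difference and the 2-SD
#' limits of agreement.
#'
#' @param x,y paired measurements.
#' @param xlab,ylab axis labels.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(x, y, xlab = "mean of pair",
                              ylab = "difference") {
  ok <- is.finite(x) & is.finite(y)
  loa <- limits_of_agreement(x[ok] - y[ok])
  df <- tibble::tibble(m = (x[ok] + y[ok]) / 2, d = x[ok] - y[ok])
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = loa$mean_difference, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = c(loa$loa_low, loa$loa_high),
                        linetype = 2, colour = "#2c7fb8") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
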