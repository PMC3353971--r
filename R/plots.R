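#' Plot an F-curve
#'
#' @param object An `f_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.f_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$F)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = if (isTRUE(attr(object, "normalized"))) "r / max chord" else "r",
                  y = "F(r)") +
    ggplot2::theme_minimal()
}

#' Plot an envelope test
#'
#' Observed F-curve over the shaded null envelope; the subtitle states the
#' decision and departure direction.
#'
#' @param object An `envelope_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.envelope_test <- function(object, ...) {
  d <- tidy(object)
  lab <- if (object$reject) {
    sprintf("CSR rejected (%s), first exit at r = %.3g",
            object$direction, object$first_exit_r)
  } else "No evidence against CSR"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), linewidth = 0.7) +
    ggplot2::labs(x = "r", y = "F(r)", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Histogram of SDI values for a study
#'
#' Under CSR the histogram should be flat; mass piling up at low values
#' signals clustering, at high values regularity.
#'
#' @param object An `sdi_study`.
#' @param bins Histogram bins (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdi_study <- function(object, bins = 10, ...) {
  ggplot2::ggplot(object$values, ggplot2::aes(x = .data$sdi)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "SDI", y = "nuclei",
                  subtitle = sprintf("K-S D = %.3f, p = %.3g",
                                     object$ks$statistic, object$ks$p_value)) +
    ggplot2::theme_minimal()
}

#' Shape-heterogeneity scatter plot
#'
#' Cube of the maximum chord against enclosed volume, one point per nucleus,
#' coloured by shape class. Scaled copies of a single shape fall on a line
#' through the origin.
#'
#' @param report Output of [shape_heterogeneity_report()] (or a collection
#'   tibble, which is summarised first).
#' @return A ggplot.
#' @export
plot_shape_heterogeneity <- function(report) {
  if (!all(c("volume", "max_chord3") %in% names(report))) {
    report <- shape_heterogeneity_report(report)
  }
  ggplot2::ggplot(report, ggplot2::aes(x = .data$volume, y = .data$max_chord3,
                                       colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "volume", y = "max chord cubed", colour = "shape class") +
    ggplot2::theme_minimal()
}

#' Power curves across expected pattern sizes
#'
#' @param power_tbl Output of [run_power_study()] or rows from the power
#'   runners.
#' @return A ggplot of power against expected pattern size, one line per
#'   process, faceted by test variant.
#' @export
plot_power <- function(power_tbl) {
  ggplot2::ggplot(power_tbl,
                  ggplot2::aes(x = .data$expected_n, y = .data$power,
                               colour = .data$process)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~variant) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "expected number of points", y = "power") +
    ggplot2::theme_minimal()
}
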