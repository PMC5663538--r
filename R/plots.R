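# ggplot2 views of the result types.

#' Plot a residence-time distribution
#'
#' @param object A [residence_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot residence_distribution
#' @export
autoplot.residence_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$prop)) +
    ggplot2::geom_col(width = attr(object, "bin_width"),
                      fill = "grey35", colour = "white") +
    ggplot2::labs(x = "elution time (s)", y = "fraction of eluted cells",
                  subtitle = sprintf("%d eluted, %d censored",
                                     attr(object, "n_eluted"),
                                     attr(object, "n_censored"))) +
    ggplot2::theme_minimal()
}

#' Plot the residence histogram of a population summary
#'
#' @param object A [summarize_population()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot population_summary
#' @export
autoplot.population_summary <- function(object, ...) {
  autoplot.residence_distribution(object$residence) +
    ggplot2::labs(title = sprintf("%% rolling = %.1f, mean %%BT = %.2f",
                                  object$pct_rolling,
                                  object$mean_pct_binding_time))
}

#' Histogram of per-cell instantaneous velocities with the rolling threshold
#'
#' @param records A [cell_records()] table.
#' @param condition The [flow_condition()] (supplies the threshold line).
#' @param binwidth Histogram bin width (um/s).
#' @return A ggplot.
#' @export
plot_velocity_distribution <- function(records, condition, binwidth = 25) {
  eluted <- records[records$adhesion_class != "censored", , drop = FALSE]
  ggplot2::ggplot(eluted, ggplot2::aes(x = .data$v_inst_median)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = condition$v_roll_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "median instantaneous velocity (um/s)", y = "cells",
                  subtitle = sprintf("rolling threshold %g um/s at %g dyn/cm2",
                                     condition$v_roll_threshold,
                                     condition$tau_wall)) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table
#'
#' @param tbl A [dose_response_table()] result.
#' @param x Name of the grouping column to put on the x axis.
#' @return A ggplot of group means with SEM error bars.
#' @export
plot_dose_response <- function(tbl, x) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data[[x]], y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey50") +
    ggplot2::labs(y = "group mean +/- SEM") +
    ggplot2::theme_minimal()
}
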