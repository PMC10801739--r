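#' Plotting
#'
#' `autoplot()` methods give quick ggplot2 views of trajectories, SPM
#' results and cohort outcome tables.
#'
#' @name plotting
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the flexion angle history of a trajectory
#'
#' @param object a `spinedyn_trajectory`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spinedyn_trajectory <- function(object, ...) {
  r <- rom(object)
  df <- tibble::tibble(time = object$times, angle = r$angle_deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$angle)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time [s]", y = "L1 flexion angle [deg]",
                  title = sprintf("%s %s: RoM %.1f deg",
                                  object$subject_id %||% "",
                                  object$technique %||% "", r$rom_deg)) +
    ggplot2::theme_minimal()
}

#' Plot an SPM z-curve with its critical threshold and clusters
#'
#' @param object a `spinedyn_spm`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spinedyn_spm <- function(object, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$z)) +
    ggplot2::geom_hline(yintercept = c(-object$z_crit, object$z_crit),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time [s]", y = "z score",
                  title = sprintf("SPM paired t-test (critical z = %.2f)",
                                  object$z_crit)) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = object$clusters,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE)
  }
  gg
}

#' Boxplots of cohort outcomes by technique
#'
#' @param outcomes tibble from [outcome_table()].
#' @param quantity outcome column to plot.
#' @return a ggplot faceted by level.
#' @export
plot_outcomes <- function(outcomes, quantity = "M_FE") {
  ggplot2::ggplot(
    outcomes,
    ggplot2::aes(x = factor(.data$technique, levels = TECHNIQUES),
                 y = .data[[quantity]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~level, scales = "free_y") +
    ggplot2::labs(x = NULL, y = quantity) +
    ggplot2::theme_minimal()
}
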