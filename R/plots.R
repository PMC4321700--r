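# ggplot2 graphics for each result type.

#' Plot centroid trajectories
#'
#' @param trajs Trajectory tibble.
#' @param colour_by Column mapped to colour (`"animal_id"` or, for
#'   simulated cohorts, `"group"`).
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajs, colour_by = "animal_id") {
  validate_trajectories(trajs)
  ggplot2::ggplot(trajs,
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               group = .data$animal_id,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' @rdname curving_histogram
#' @param object A `curving_histogram` tibble.
#' @param ... Unused.
#' @method autoplot curving_histogram
#' @export
autoplot.curving_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid, y = .data$weight_mm)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "curving rate (deg/mm, ventral positive)",
                  y = "path length (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname cohort_log_summary
#' @param object A `cohort_log_summary` tibble.
#' @param ... Unused.
#' @method autoplot cohort_log_summary
#' @export
autoplot.cohort_log_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta_mm, y = .data$median_log10)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q1_log10,
                                        ymax = .data$q3_log10),
                           width = 0.02) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(delta ~ "(mm)"),
                  y = expression(median ~ log[10](L[delta] / L[0]))) +
    ggplot2::theme_minimal()
}

#' Plot cohort ratio curves on log-log axes
#'
#' One faint curve per animal with the cohort median-of-log overlaid.
#'
#' @param results A `ratio_curve` tibble.
#' @return A ggplot.
#' @export
plot_ratio_curves <- function(results) {
  summary <- cohort_log_summary(results)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$delta_mm, y = log10(.data$ratio),
                               group = .data$animal_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey50") +
    ggplot2::geom_line(data = summary,
                       ggplot2::aes(x = .data$delta_mm,
                                    y = .data$median_log10, group = 1),
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(delta ~ "(mm)"),
                  y = expression(log[10](L[delta] / L[0]))) +
    ggplot2::theme_minimal()
}

#' Plot a head-angle trace with detected bends
#'
#' @param series Head-angle tibble from [head_angle_series()].
#' @param bends Optional `bend_summary` from [extract_bends()]; detected
#'   bends are marked.
#' @return A ggplot.
#' @export
plot_head_angles <- function(series, bends = NULL) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$t_s, y = .data$angle_deg)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "time (s)",
                  y = "head angle (deg, ventral positive)") +
    ggplot2::theme_minimal()
  if (!is.null(bends) && nrow(bends) > 0) {
    p <- p + ggplot2::geom_point(
      data = bends,
      ggplot2::aes(x = .data$t_s, y = .data$angle_deg, colour = .data$side)
    ) +
      ggplot2::labs(colour = "bend")
  }
  p
}

#' @rdname classify_cl
#' @param object A `loop_report` tibble.
#' @param ... Unused.
#' @method autoplot loop_report
#' @export
autoplot.loop_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cl_class, y = .data$loopy_fraction)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.30, linetype = 2, colour = "red") +
    ggplot2::labs(x = "class", y = "loopy path fraction") +
    ggplot2::theme_minimal()
}
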