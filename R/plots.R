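#' Boxplots of session distributions with percentile whiskers
#'
#' Draws the per-session distribution of average angles (or scores) for each
#' group and exercise as boxplots whose whiskers sit at the 10th and 90th
#' percentiles, with extreme values as points beyond the whiskers.
#'
#' @param object A `progress_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progress_report <- function(object, ...) {
  s <- object$summaries
  pts <- s |>
    dplyr::select("group", "exercise_id", "session", "outliers") |>
    tidyr::unnest_longer("outliers", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$session))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity", width = 0.6, fill = "grey85"
    ) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$value), size = 0.8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$exercise_id),
      cols = ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(x = "session", y = "average angle (degrees)") +
    ggplot2::theme_minimal()
}

#' Plot a controlled-angle trajectory
#'
#' Convenience view of a frame stream: the per-frame angle at a joint over
#' time, e.g. the knee angle during a squat.
#'
#' @param stream A `frame_stream`.
#' @param a,vertex,c Joints passed to [joint_angle()].
#' @return A ggplot object.
#' @export
plot_joint_angle <- function(stream, a, vertex, c) {
  arr <- stream_arrays(stream)
  df <- tibble::tibble(time = arr$time,
                       angle = joint_angle(stream, a, vertex, c))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = sprintf("angle at %s (degrees)", vertex)) +
    ggplot2::theme_minimal()
}
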