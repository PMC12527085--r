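#' Plot an out-of-bag error curve
#'
#' Mean OOB misclassification error as a function of grown trees, with a
#' plus/minus one SD ribbon over the runs.
#'
#' @param object an `oob_curve` tibble (optionally with a `model`
#'   column to facet by).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.oob_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$trees, y = .data$mean_oob)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_oob - .data$sd_oob,
                                      ymax = .data$mean_oob + .data$sd_oob),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Grown trees", y = "OOB classification error") +
    ggplot2::theme_minimal()
  if ("model" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$model))
  }
  p
}

#' Plot detected Sit phases over a trial timeline
#'
#' Ground-truth SIT intervals (top band), detected Sit phases (second
#' band) and, optionally, the vertical acceleration trace beneath.
#'
#' @param object a `sit_phases` tibble.
#' @param truth optional [label_track] with ground-truth SIT intervals.
#' @param recording optional [imu_recording] whose `acc_z` channel is
#'   drawn under the bands.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sit_phases <- function(object, truth = NULL, recording = NULL, ...) {
  bands <- tibble(start_s = object$start_s, end_s = object$end_s,
                  what = "detected")
  if (!is.null(truth)) {
    tr <- track_intervals(truth, "SIT")
    bands <- bind_rows(bands, tibble(start_s = tr$start_s, end_s = tr$end_s,
                                     what = "manual"))
  }
  bands$ymin <- ifelse(bands$what == "manual", 1.25, 1.05)
  bands$ymax <- bands$ymin + 0.15
  p <- ggplot2::ggplot()
  if (!is.null(recording)) {
    p <- p + ggplot2::geom_line(
      data = tibble(t = recording$t, acc = recording$acc_z),
      ggplot2::aes(x = .data$t, y = .data$acc), colour = "grey60",
      linewidth = 0.2)
  }
  p +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$what)) +
    ggplot2::scale_fill_manual(values = c(detected = "grey35",
                                          manual = "goldenrod2"),
                               name = NULL) +
    ggplot2::labs(x = "Time (s)", y = "Vertical acceleration (g)") +
    ggplot2::theme_minimal()
}

#' Boxplot of segmentation timing errors
#'
#' One box per trial length, annotated with the number of segmentation
#' points and the Tukey outlier percentage.
#'
#' @param report a `sit_report` from [run_pipeline()].
#' @return a ggplot object.
#' @export
plot_delta_t <- function(report) {
  dts <- report$trials |>
    mutate(dt = map(.data$eval, function(e) e$delta_t)) |>
    select("duration_s", "dt") |>
    tidyr::unnest("dt")
  labs <- dts |>
    group_by(.data$duration_s) |>
    summarise(n = dplyr::n(),
              pct = boxplot_outliers(.data$delta_t_s)$pct_outliers,
              top = max(.data$delta_t_s), .groups = "drop")
  ggplot2::ggplot(dts, ggplot2::aes(x = factor(.data$duration_s / 60),
                                    y = .data$delta_t_s)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 1) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = factor(.data$duration_s / 60),
                                    y = .data$top,
                                    label = sprintf("N = %d\n%%out = %.1f",
                                                    .data$n, .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Trial length (min)", y = expression(Delta * T ~ "(s)")) +
    ggplot2::theme_minimal()
}
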