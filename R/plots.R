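#' Plot a gaze trace with schedule annotations
#'
#' Horizontal gaze angle over time; response-window onsets are marked when a
#' schedule is supplied.
#'
#' @param object A `gaze_trace`.
#' @param schedule Optional `stimulus_schedule` for onset markers.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gaze_trace <- function(object, schedule = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$gaze_h)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "horizontal gaze (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(schedule)) {
    resp <- response_events(schedule, recorded_only = FALSE)
    p <- p + ggplot2::geom_vline(xintercept = resp$t_onset,
                                 colour = "red", alpha = 0.3,
                                 linetype = "dashed")
  }
  p
}

#' Stabilogram with its convex envelope
#'
#' COP trajectory in the ML/AP plane overlaid with the convex envelope whose
#' area is the AEC metric.
#'
#' @param object A `cop_trace`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cop_trace <- function(object, ...) {
  hull <- convex_hull(cbind(object$x_ml, object$y_ap))
  hull_df <- tibble::tibble(x_ml = hull[, 1], y_ap = hull[, 2])
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_ml, y = .data$y_ap)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.6) +
    ggplot2::geom_polygon(data = hull_df, fill = NA, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "medio-lateral (mm)", y = "anterior-posterior (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a pupil power spectral density
#'
#' @param object A `pupil_psd`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pupil_psd <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$frequency, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::labs(x = "frequency (Hz)", y = "density (mm²/Hz)") +
    ggplot2::theme_minimal()
}

#' Effect-size overview of the pairwise battery
#'
#' Dot plot of Wilcoxon effect sizes per comparison, faceted by parameter,
#' with adjusted-significance highlighting and the small/moderate/large
#' threshold guides at 0.1 / 0.3 / 0.5.
#'
#' @param object A `pairwise_wilcoxon` tibble.
#' @param alpha Significance level applied to adjusted p values.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pairwise_wilcoxon <- function(object, alpha = 0.05, ...) {
  d <- dplyr::mutate(
    tibble::as_tibble(object),
    comparison = paste0("#", .data$condition_a, " vs #", .data$condition_b),
    significant = .data$p_adjusted < alpha
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect_size,
                                  y = .data$comparison,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(0.1, 0.3, 0.5), linetype = "dotted") +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = "effect size r", y = NULL) +
    ggplot2::theme_minimal()
}

#' Association-matrix heatmap
#'
#' @param object An `assoc_matrix`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.assoc_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter_a,
                                  y = .data$parameter_b,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Spearman rho, condition",
                                object$condition)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
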