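#' Plot an intensity profile
#'
#' Line plot of intensity against position, with called gaps (if a
#' `gap_report` is supplied) shaded.
#'
#' @param object An [intensity_profile()].
#' @param gaps Optional [detect_gaps()] result to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_profile <- function(object, gaps = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position_um,
                                    y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "position (µm)", y = "intensity (0-255)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (!is.null(gaps) && nrow(gaps)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(gaps), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_um, xmax = .data$end_um,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15
    )
  }
  p
}

#' Plot a FRAP fit
#'
#' Normalized post-bleach recovery points with the fitted single-exponential
#' curve and the plateau fraction.
#'
#' @param object A `frap_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$t_post_s, y = .data$normalized)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "steelblue") +
    ggplot2::geom_hline(yintercept = object$A, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(
      x = "time after bleach (s)", y = "normalized intensity",
      title = sprintf("A = %.3f, k = %.4f /s, t1/2 = %.1f s",
                      object$A, object$k, object$t_half_s)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a kymograph
#'
#' Raster of intensity over position (vertical) and time (horizontal);
#' moving structures appear as sloped streaks.
#'
#' @param object A `kymograph` from [build_kymograph()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- expand.grid(
    position_um = (seq_len(nrow(object)) - 1) * attr(object, "pixel_size_um"),
    time_s = (seq_len(ncol(object)) - 1) * attr(object, "frame_interval_s")
  )
  df$intensity <- as.vector(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$position_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "position (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a group comparison
#'
#' Strip plot of the unit-level datapoints per group with group means,
#' titled with the test performed and its p-value.
#'
#' @param object An `er_comparison` from [compare_groups()].
#' @param value,group Column names used in the comparison.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.er_comparison <- function(object, value = "value", group = "group",
                                   ...) {
  df <- object$data
  df$.value <- df[[value]]
  df$.group <- factor(df[[group]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.group, y = .data$.value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, color = "firebrick") +
    ggplot2::labs(x = NULL, y = value,
                  title = sprintf("%s, p = %.3g", object$test,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
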