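#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_abline facet_wrap labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a line-scan image
#'
#' @param object A `linescan` or `normalized_linescan`.
#' @param ... Unused.
#' @return A ggplot: space (um) against time (s), fluorescence as fill.
#' @method autoplot linescan
#' @export
autoplot.linescan <- function(object, ...) {
  df <- linescan_as_df(object$values, object$pixel_size_um,
                       object$line_rate_hz)
  ggplot(df, aes(.data$time_s, .data$position_um, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "F (a.u.)") +
    labs(x = "time (s)", y = "position (µm)") +
    theme_minimal()
}

#' @rdname autoplot.linescan
#' @method autoplot normalized_linescan
#' @export
autoplot.normalized_linescan <- function(object, ...) {
  df <- linescan_as_df(object$dff0, object$pixel_size_um,
                       object$line_rate_hz)
  ggplot(df, aes(.data$time_s, .data$position_um, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(Delta * F / F[0])) +
    labs(x = "time (s)", y = "position (µm)") +
    theme_minimal()
}

linescan_as_df <- function(m, pixel_size_um, line_rate_hz) {
  tibble(
    position_um = rep((seq_len(nrow(m)) - 0.5) * pixel_size_um, ncol(m)),
    time_s = rep((seq_len(ncol(m)) - 1) / line_rate_hz, each = nrow(m)),
    value = as.vector(m))
}

#' Plot spark-parameter kernel density estimates
#'
#' @param object A `spark_summary`.
#' @param ... Unused.
#' @return A ggplot of per-parameter KDE curves.
#' @method autoplot spark_summary
#' @export
autoplot.spark_summary <- function(object, ...) {
  df <- purrr::imap_dfr(object$kde, function(k, nm) {
    dplyr::mutate(k, parameter = nm)
  })
  ggplot(df, aes(.data$x, .data$density)) +
    geom_line() +
    facet_wrap(~parameter, scales = "free") +
    labs(x = NULL, y = "density") +
    theme_minimal()
}

#' Poincare plot of beat-to-beat variability
#'
#' @param object A `beat_series`.
#' @param which `"bp"` (beat period) or `"fpdcf"`.
#' @param ... Unused.
#' @return A ggplot of beat n against beat n - 1 with the identity line.
#' @method autoplot beat_series
#' @export
autoplot.beat_series <- function(object, which = c("bp", "fpdcf"), ...) {
  which <- match.arg(which)
  df <- if (which == "bp") object$poincare_bp else object$poincare_fpdcf
  if (is.null(df)) abort("no pairs available", class = "myospark_input_error")
  lab <- if (which == "bp") "beat period (s)" else "FPDcF (s)"
  ggplot(df, aes(.data$previous, .data$current)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_point(alpha = 0.7) +
    labs(x = paste(lab, "at beat n-1"), y = paste(lab, "at beat n")) +
    theme_minimal()
}

#' Plot a leak/load protocol trace with its phase segmentation
#'
#' @param trace Tibble `time_s`, `value`.
#' @param seg Phase tibble from [segment_phases()].
#' @return A ggplot of the trace with phase boundaries.
#' @export
plot_leakload_trace <- function(trace, seg = NULL) {
  p <- ggplot(trace, aes(.data$time_s, .data$value)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "fluorescence (a.u.)") +
    theme_minimal()
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_vline(xintercept = seg$start_s[-1],
                                 linetype = "dotted", colour = "red")
  }
  p
}
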