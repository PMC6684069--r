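#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: recordings
#' (stacked traces), gliding R-vector traces with detected coupled intervals,
#' model-selection summaries and symmetrised strength tables. Plots are
#' descriptive outputs only; no computation consumes them.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @param max_seconds Trace plots show at most this many seconds.
#' @name autoplot-cpgnet
NULL

#' @rdname autoplot-cpgnet
#' @export
autoplot.cpg_recording <- function(object, max_seconds = 60, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$time <= min(.data$time) + max_seconds)
  long <- tidyr::pivot_longer(df, -"time", names_to = "channel")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @rdname autoplot-cpgnet
#' @param r_window_threshold Threshold line drawn on the R trace.
#' @export
autoplot.cpg_rvector <- function(object, r_window_threshold = 0.8, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$time, .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = r_window_threshold, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "R (15 s window)")
}

#' @rdname autoplot-cpgnet
#' @export
autoplot.cpg_coupling <- function(object, ...) {
  p <- autoplot(object$rvector, ...)
  if (nrow(object$intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1),
      inherit.aes = FALSE, alpha = 0.2
    )
  }
  p + ggplot2::ggtitle(paste(object$pair, collapse = " ~ "))
}

#' @rdname autoplot-cpgnet
#' @export
autoplot.cpg_bms <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df, c("rel_log_evidence", "posterior"))
  ggplot2::ggplot(long, ggplot2::aes(.data$model_id, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$name), scales = "free_y") +
    ggplot2::labs(x = "model", y = NULL)
}

#' Boxplot of symmetrised, normalised coupling strengths per connection class
#'
#' @param strengths Output of [summarize_strengths()].
#' @return A ggplot.
#' @export
plot_strengths <- function(strengths) {
  per_fit <- attr(strengths, "per_fit")
  ggplot2::ggplot(per_fit, ggplot2::aes(.data$class, .data$strength)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "coupling strength (a.u.)")
}
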