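#' Plot a reactivity-rate histogram
#'
#' Draws the binned rate distribution produced by [rate_histogram()];
#' the under- and overflow bins are dropped from the plot. Real probing
#' data pile up in the first bins, so a zoomed companion panel over
#' `[0, 0.1]` is often informative (`xlim`).
#'
#' @param histogram Tibble from [rate_histogram()].
#' @param xlim Optional x-axis limits, e.g. `c(0, 0.1)` for the zoomed
#'   view.
#' @return A ggplot object.
#' @export
plot_rate_histogram <- function(histogram, xlim = NULL) {
  h <- filter(histogram, is.finite(.data$bin_start), is.finite(.data$bin_end))
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = h$bin_end[1] - h$bin_start[1],
                      fill = "steelblue", colour = NA) +
    ggplot2::labs(x = "stop / mutation rate", y = "number of bases")
  if (!is.null(xlim)) p <- p + ggplot2::coord_cartesian(xlim = xlim)
  p
}

#' Plot the top-x% unpaired-fraction curve of a run report
#'
#' @param report A `run_report` from [pipeline_evaluate()] with a
#'   non-`NULL` `top_x_curve`.
#' @return A ggplot object.
#' @export
plot_top_x_curve <- function(report) {
  if (is.null(report$top_x_curve)) {
    abort("report carries no top-x curve (degenerate labels?).",
          class = "probeval_validation_error")
  }
  ggplot2::ggplot(report$top_x_curve,
                  ggplot2::aes(x = .data$x, y = .data$fraction_unpaired)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "top x% of reactivity",
                  y = "fraction unpaired among selected bases")
}

#' @rdname reactivity_profile
#' @param object A `reactivity_profile`.
#' @param ... Unused.
#' @method autoplot reactivity_profile
#' @export
autoplot.reactivity_profile <- function(object, ...) {
  d <- as_tibble(object) |> filter(.data$valid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$reactivity)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "position (1-based)", y = "reactivity",
                  title = rna_id(object))
}
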