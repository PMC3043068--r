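#' Plot a windowed track
#'
#' @param track Track tibble from [windowed_gc()], [gc_skew()],
#'   [oligo_skew()] or [novelty_track()].
#' @return A ggplot object.
#' @export
plot_track <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                      y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL)
}

#' @rdname gc_histogram
#' @param object A `gc_distribution`.
#' @param ... Ignored.
#' @export
autoplot.gc_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = 0.009, fill = "grey30") +
    ggplot2::geom_vline(xintercept = object$mode, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "read G+C fraction", y = "reads")
}

#' Plot a bias profile's per-segment amplification gain
#'
#' @param profile Tibble from [simulate_bias_profile()].
#' @param depth Depth at which to draw the expected-coverage line.
#' @return A ggplot object.
#' @export
plot_bias_profile <- function(profile, depth = 20) {
  seg <- recoverable_segments(profile, depth = depth)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$exp_depth,
                                       yend = .data$exp_depth,
                                       colour = .data$recoverable)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "position (bp)", y = "expected depth (log)")
}
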