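#' Plot a smoothed genome-wide track
#'
#' One panel per chromosome, window centres on the x axis (Mb). Delineated
#' regions, if supplied, are shaded.
#'
#' @param track Track tibble from [smooth_track()] or [tajima_track()].
#' @param regions Optional region tibble from [delineate_regions()].
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_track <- function(track, regions = NULL, ylab = "statistic") {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = .data$center / 1e6, y = .data$value))
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.4,
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Autoplot a scan result
#'
#' Smoothed FST of the overall oceanic-freshwater comparison with the
#' delineated candidate regions shaded.
#'
#' @param object A `radscan_result`.
#' @param track Which track to draw (default `"overall"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.radscan_result <- function(object, track = "overall", ...) {
  plot_track(object$tracks[[track]], regions = object$regions,
             ylab = paste0("smoothed FST (", track, ")"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
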