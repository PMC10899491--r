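# Per-chromosome association track plots: raw statistic as points, fitted
# curve as a line, threshold / confidence bounds as dashed lines, called
# regions shaded.

#' Plot a bsa_scan
#'
#' One panel per chromosome: colored points are the per-site raw statistic,
#' the black line is the fitted value, dashed red lines mark the
#' association threshold (ED) or the null confidence bounds (delta
#' SNP-index), and called regions are shaded.
#'
#' @param object A `bsa_scan`.
#' @param point_alpha Point transparency (default 0.3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_scan
#' @export
autoplot.bsa_scan <- function(object, point_alpha = 0.3, ...) {
  sites <- object$sites
  track <- object$track
  if (nrow(track) == 0) {
    warn("empty track: returning a placeholder panel")
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty track"))
  }
  ylab <- if (object$statistic == "ED5") {
    paste0("ED^", object$params$power %||% 5)
  } else {
    expression(Delta * " SNP-index")
  }
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab) +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25
    )
  }
  p <- p + ggplot2::geom_point(
    data = sites,
    ggplot2::aes(x = .data$pos / 1e6, y = .data$raw, colour = .data$chrom),
    alpha = point_alpha, size = 0.5, show.legend = FALSE
  ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black")
  if (object$statistic == "ED5") {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = "dashed", colour = "red")
  } else {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$upper),
                         linetype = "dashed", colour = "red") +
      ggplot2::geom_line(ggplot2::aes(y = .data$lower),
                         linetype = "dashed", colour = "red")
  }
  p
}

#' Save a track plot to a file
#'
#' @param scan A `bsa_scan`.
#' @param path Output image path (device chosen from the extension).
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_track_plot <- function(scan, path, width = 9, height = 5) {
  ggplot2::ggsave(path, autoplot(scan), width = width, height = height)
  invisible(path)
}
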