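#' Space-time velocity heatmap
#'
#' Renders a velocity map as a heatmap with arc-length position on the
#' x-axis and time on the y-axis; signed velocity (mm/s) on a diverging
#' scale. Optional arrows under the map summarise the mean velocity in the
#' beginning, middle and end thirds of the segment.
#'
#' @param object A `velocity_map`.
#' @param arrows Draw the begin/middle/end summary arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_map <- function(object, arrows = TRUE, ...) {
  dt <- attr(object, "dt") %||% 1
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$time,
                                    fill = .data$velocity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "velocity\n(mm/s)") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position along centerline (mm)", y = "time (s)") +
    ggplot2::theme_minimal()
  if (arrows) {
    L <- attr(object, "segment_length") %||% max(object$position)
    met <- aggregate_metrics(object)
    three <- three_part_means(met)
    arr <- dplyr::summarise(dplyr::group_by(three, .data$part),
                            velocity = mean(.data$velocity),
                            .groups = "drop")
    centers <- c(begin = L / 6, middle = L / 2, end = 5 * L / 6)
    arr$x <- centers[as.character(arr$part)]
    y_arrow <- max(object$time) + 1.5 * dt
    p <- p + ggplot2::geom_segment(
      data = arr,
      ggplot2::aes(x = .data$x - .data$velocity * 2,
                   xend = .data$x + .data$velocity * 2,
                   y = y_arrow, yend = y_arrow),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 0.8, inherit.aes = FALSE
    )
  }
  p
}

#' @export
plot.velocity_map <- function(x, ...) print(autoplot.velocity_map(x, ...))

#' Mid-slice view of a phantom frame
#'
#' @param object A `cine_phantom`.
#' @param frame 1-based frame to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cine_phantom <- function(object, frame = 1, ...) {
  vol <- object$frames[[frame]]
  k <- ceiling(dim(vol$voxels)[3] / 2)
  sl <- vol$voxels[, , k]
  df <- expand.grid(
    x = vol$origin[1] + (seq_len(nrow(sl)) - 1) * vol$spacing[1],
    y = vol$origin[2] + (seq_len(ncol(sl)) - 1) * vol$spacing[2]
  )
  df$intensity <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("phantom frame %d, slice z=%d", frame, k)) +
    ggplot2::theme_minimal()
}
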