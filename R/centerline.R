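#' Centerline objects
#'
#' A centerline is an ordered 3D polyline through the middle of a tubular
#' intestinal segment, stored as a tibble in world millimetres with one row
#' per point and columns `x`, `y`, `z`, `arc_length` (cumulative distance
#' from the first point), and the unit tangent components `tx`, `ty`, `tz`.
#' The resampling step (mm) and the cine frame in which the centerline was
#' traced are carried as attributes.
#'
#' @param x A centerline, or an object to convert: a matrix or data frame
#'   with 3 coordinate columns (named `x`, `y`, `z` or `x_mm`, `y_mm`,
#'   `z_mm`, or the first three columns).
#' @name centerline
NULL

new_centerline <- function(pts, step, frame_index) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  tang <- polyline_tangents(pts)
  out <- tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    arc_length = arc,
    tx = tang[, 1], ty = tang[, 2], tz = tang[, 3]
  )
  attr(out, "step") <- step
  attr(out, "frame_index") <- frame_index
  class(out) <- c("centerline", class(out))
  out
}

centerline_points <- function(cl) {
  unname(as.matrix(cl[, c("x", "y", "z")]))
}

coerce_points <- function(x) {
  if (inherits(x, "centerline")) return(centerline_points(x))
  if (is.matrix(x)) {
    stopifnot(ncol(x) >= 3)
    return(unname(x[, 1:3, drop = FALSE]))
  }
  if (is.data.frame(x)) {
    nm <- names(x)
    pick <- function(a, b) if (all(c(a, b) %in% nm)) c(a, b) else NULL
    cols <- if (all(c("x", "y", "z") %in% nm)) c("x", "y", "z")
      else if (all(c("x_mm", "y_mm", "z_mm") %in% nm)) c("x_mm", "y_mm", "z_mm")
      else nm[1:3]
    return(unname(as.matrix(x[, cols])))
  }
  stop("cannot interpret input as 3D points", call. = FALSE)
}

#' Resample a polyline to a uniform arc-length step
#'
#' Points are placed every `step` mm along the input polyline (measured in
#' its own chordal arc length), always retaining both endpoints; the final
#' interval may be shorter than `step`. Resampling an object that is already
#' a centerline sampled at the same step returns it unchanged, so the
#' operation is idempotent.
#'
#' The default step of 1 mm is finer than the 1.4 mm in-plane voxel size and
#' makes the 8 mm smoothing window used during centerline propagation an odd
#' 9-sample kernel.
#'
#' @param x Points as accepted by [centerline] coercion (matrix, data frame,
#'   or centerline).
#' @param step Resampling step in mm (> 0).
#' @param frame_index Cine frame at which the centerline was traced.
#' @return A [centerline] tibble.
#' @export
#' @examples
#' seg <- resample_centerline(cbind(c(0, 10), 0, 0), step = 1)
#' segment_length(seg)
resample_centerline <- function(x, step = 1, frame_index = 0L) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0)
    stop("`step` must be a single positive number", call. = FALSE)
  if (inherits(x, "centerline") && isTRUE(all.equal(attr(x, "step"), step)))
    return(x)
  pts <- coerce_points(x)
  if (nrow(pts) < 2)
    stop("invalid centerline: need at least 2 distinct points", call. = FALSE)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2)
    stop("invalid centerline: need at least 2 distinct points", call. = FALSE)
  seglen <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  if (total <= 0)
    stop("invalid centerline: zero total length", call. = FALSE)
  s <- seq(0, total, by = step)
  if (total - s[length(s)] > 1e-9 * max(1, total)) s <- c(s, total)
  if (length(s) < 2) s <- c(0, total)
  out <- vapply(1:3, function(k) approx(arc, pts[, k], xout = s)$y, numeric(length(s)))
  new_centerline(matrix(out, ncol = 3), step = step, frame_index = frame_index)
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  if (n < 2) stop("invalid centerline: need at least 2 points", call. = FALSE)
  d <- matrix(NA_real_, n, 3)
  d[1, ] <- pts[2, ] - pts[1, ]
  d[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) d[2:(n - 1), ] <- pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm == 0))
    stop("invalid centerline: coincident neighbouring points", call. = FALSE)
  d / nrm
}

#' Unit tangents of a centerline
#'
#' Interior tangents by central differences of the neighbouring points,
#' endpoint tangents by one-sided differences; all normalised to unit length.
#'
#' @param x A [centerline] (>= 3 points) or coercible point set.
#' @return The centerline with refreshed `tx`, `ty`, `tz` columns.
#' @export
compute_tangents <- function(x) {
  pts <- coerce_points(x)
  if (nrow(pts) < 3)
    stop("invalid centerline: need at least 3 points for tangents", call. = FALSE)
  tang <- polyline_tangents(pts)
  if (inherits(x, "centerline")) {
    x$tx <- tang[, 1]; x$ty <- tang[, 2]; x$tz <- tang[, 3]
    x
  } else {
    new_centerline(pts, step = NA_real_, frame_index = 0L)
  }
}

#' Arc length of a centerline segment
#'
#' Total length in mm, i.e. the final cumulative arc-length value. Segments
#' of 40 mm (4 cm) or less are conventionally excluded from analysis; see
#' [apply_exclusion_filters()].
#'
#' @param x A [centerline] or coercible point set.
#' @return Length in mm.
#' @export
segment_length <- function(x) {
  pts <- coerce_points(x)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf(
    "<centerline> %d points, %.1f mm, step %s mm, frame %s\n",
    nrow(x), segment_length(x),
    format(attr(x, "step")), format(attr(x, "frame_index"))
  ))
  NextMethod()
}

# Reverse the point order of a centerline (tangents flip sign).
reverse_centerline <- function(cl) {
  pts <- centerline_points(cl)[nrow(cl):1, , drop = FALSE]
  new_centerline(pts, step = attr(cl, "step"), frame_index = attr(cl, "frame_index"))
}
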