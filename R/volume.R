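#' Cine volume objects
#'
#' One 3D scalar grid of a 4D cine-MRI acquisition. World coordinates follow
#' the scanner convention: the world position of voxel `(i, j, k)` (1-based)
#' is `origin + (i-1, j-1, k-1) * spacing`. Only axis-aligned geometries are
#' represented; oblique acquisitions must be resampled upstream.
#'
#' @param voxels 3D numeric array.
#' @param spacing Per-axis voxel size in mm (strictly positive, length 3).
#' @param origin World coordinate (mm) of the first voxel centre.
#' @param time_index Frame number within the acquisition (0-based).
#' @param dt Inter-frame interval in seconds (default 1 s, one volume per
#'   second).
#' @return An object of class `cine_volume`.
#' @export
cine_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                        time_index = 0L, dt = 1.0) {
  if (length(dim(voxels)) != 3)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values", call. = FALSE)
  if (!is.finite(dt) || dt <= 0)
    stop("`dt` must be strictly positive", call. = FALSE)
  structure(
    list(
      voxels = voxels, spacing = spacing, origin = as.numeric(origin),
      time_index = as.integer(time_index), dt = dt
    ),
    class = "cine_volume"
  )
}

#' @export
print.cine_volume <- function(x, ...) {
  cat(sprintf(
    "<cine_volume> %s voxels, spacing %s mm, frame %d, dt %.3g s\n",
    paste(dim(x$voxels), collapse = "x"),
    paste(format(x$spacing), collapse = " x "),
    x$time_index, x$dt
  ))
  invisible(x)
}

# World-space extent (mm) of the voxel-centre lattice.
volume_extent <- function(vol) {
  vol$origin + (dim(vol$voxels) - 1) * vol$spacing
}

#' Voxel-centre world coordinates of a volume
#'
#' @param vol A [cine_volume()].
#' @return n x 3 matrix of world coordinates (mm), x fastest.
#' @export
voxel_coordinates <- function(vol) {
  d <- dim(vol$voxels)
  g <- expand.grid(
    x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
    y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
    z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  )
  as.matrix(g)
}

#' Interpolate a cine volume at world coordinates
#'
#' Trilinear interpolation with clamped (constant) extrapolation outside
#' the grid.
#'
#' @param vol A [cine_volume()].
#' @param xyz n x 3 world coordinates (mm).
#' @return Numeric vector of intensities.
#' @export
sample_volume <- function(vol, xyz) {
  interp_trilinear(vol$voxels, vol$origin, vol$spacing, xyz)
}

# TRUE for points within the voxel-centre bounding box of the volume.
in_fov <- function(vol, xyz) {
  ext <- volume_extent(vol)
  xyz[, 1] >= vol$origin[1] & xyz[, 1] <= ext[1] &
    xyz[, 2] >= vol$origin[2] & xyz[, 2] <= ext[2] &
    xyz[, 3] >= vol$origin[3] & xyz[, 3] <= ext[3]
}
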