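#' Read a 4D cine-MRI acquisition
#'
#' Loads a 4D NIfTI-1 file as a list of [cine_volume()]s in acquisition
#' order. World coordinates derive from the NIfTI affine, which must be
#' axis-aligned (diagonal, positive scales); oblique acquisitions must be
#' resampled upstream. The inter-frame interval is read from the time-axis
#' pixdim when present, otherwise `dt` is used. The first `discard_frames`
#' volumes are dropped with a notice (the first two volumes of a scan
#' typically contain contrast artifacts).
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param discard_frames Leading frames to drop (default 2).
#' @param dt Fallback inter-frame interval (s).
#' @return List of [cine_volume()]s.
#' @export
read_cine <- function(path, discard_frames = 2L, dt = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4)
    stop(sprintf("expected a 4D cine volume, got a %dD image", length(d)),
         call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-4 * max(abs(diag(rot)))))
    stop("degenerate or oblique affine: only axis-aligned volumes are supported",
         call. = FALSE)
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) stop("degenerate affine: non-positive spacing",
                              call. = FALSE)
  origin <- xf[1:3, 4]
  pd <- attr(img, "pixdim")
  dt_file <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else dt
  arr <- as.array(img)
  n_t <- d[4]
  discard_frames <- min(as.integer(discard_frames), n_t - 1L)
  if (discard_frames > 0)
    message(sprintf("discarding the first %d frame(s) of %d", discard_frames, n_t))
  lapply(seq.int(discard_frames + 1L, n_t), function(t) {
    cine_volume(arr[, , , t], spacing = spacing, origin = origin,
                time_index = t - 1L - discard_frames, dt = dt_file)
  })
}

#' Write a cine frame sequence as a 4D NIfTI-1 file
#'
#' @param frames List of [cine_volume()]s on a common grid.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_cine <- function(frames, path) {
  v1 <- frames[[1]]
  arr <- array(0, c(dim(v1$voxels), length(frames)))
  for (t in seq_along(frames)) arr[, , , t] <- frames[[t]]$voxels
  img <- RNifti::asNifti(arr)
  aff <- diag(4)
  diag(aff)[1:3] <- v1$spacing
  aff[1:3, 4] <- v1$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  img$pixdim <- c(img$pixdim[1], v1$spacing, v1$dt, img$pixdim[6:8])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ordered 3D centerline
#'
#' Accepts CSV with an `x_mm,y_mm,z_mm` (or `x,y,z`) header, one point per
#' row in order, or a JSON array of `[x, y, z]` triples; coordinates in
#' world millimetres in the same frame as the NIfTI affine.
#'
#' @param path CSV or JSON file.
#' @param fov Optional [cine_volume()]: warn when points fall outside its
#'   bounds.
#' @return n x 3 matrix of points (mm).
#' @export
read_centerline <- function(path, fov = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pts <- if (ext == "json") {
    lst <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (!is.matrix(lst) || ncol(lst) != 3)
      stop("malformed centerline JSON: expected a list of [x, y, z]",
           call. = FALSE)
    lst
  } else {
    df <- utils::read.csv(path)
    nm <- names(df)
    cols <- if (all(c("x_mm", "y_mm", "z_mm") %in% nm)) c("x_mm", "y_mm", "z_mm")
      else if (all(c("x", "y", "z") %in% nm)) c("x", "y", "z")
      else stop("malformed centerline CSV: need x_mm,y_mm,z_mm header",
                call. = FALSE)
    as.matrix(df[, cols])
  }
  if (!is.numeric(pts) || anyNA(pts))
    stop("malformed centerline file: non-numeric rows", call. = FALSE)
  if (nrow(pts) < 2)
    stop("invalid centerline: need at least 2 points", call. = FALSE)
  if (!is.null(fov) && !all(in_fov(fov, pts)))
    warning("centerline points fall outside the image bounds")
  unname(pts)
}

#' Write a centerline as CSV
#'
#' @param x A [centerline] or point matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(x, path) {
  pts <- coerce_points(x)
  utils::write.csv(
    data.frame(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a space-time velocity map as tidy CSV
#'
#' Columns: `position_mm`, `time_s`, `velocity_mm_per_s`, `reliable_flag`.
#'
#' @param map A `velocity_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_velocity_map <- function(map, path) {
  utils::write.csv(
    data.frame(
      position_mm = map$position, time_s = map$time,
      velocity_mm_per_s = map$velocity, reliable_flag = map$reliable
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a segment table CSV
#'
#' @param path CSV with one [segment_table] row per segment.
#' @return A tibble.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "subject_id")
  if (!all(need %in% names(df)))
    stop("segment table must contain segment_id and subject_id columns",
         call. = FALSE)
  if ("duplicate_of" %in% names(df))
    df$duplicate_of <- ifelse(df$duplicate_of %in% c("", "NA"),
                              NA_character_, as.character(df$duplicate_of))
  tibble::as_tibble(df)
}

# Serialise a run configuration (resolved settings + seed) beside outputs,
# so every run can be reproduced.
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
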