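#' Differential sampling parameters for spurious-motion suppression
#'
#' Breathing, cardiac and adjacent-loop motion affect both the segment of
#' interest and its surroundings, while intestinal motility is local to the
#' lumen. Subtracting the mean motion over a large disc (30 mm diameter,
#' larger than the small-intestine diameter, expandable for severely
#' distended segments) from the mean motion over a small disc (0.5 mm) at
#' each centerline point removes this common-mode component, in the manner
#' of common-mode rejection in electronics.
#'
#' Both discs lie in the plane orthogonal to the local centerline tangent
#' and are sampled with a deterministic low-discrepancy (sunflower) pattern,
#' so repeated runs are free of Monte-Carlo jitter. Means are
#' area-normalised so that the common component cancels exactly.
#'
#' @param inner_diameter Inner disc diameter (mm).
#' @param outer_diameter Outer disc diameter (mm); must exceed the inner
#'   and stay within the registration tube.
#' @param inner_samples,outer_samples Sample points per disc.
#' @return A `sampling_params` list.
#' @export
sampling_params <- function(inner_diameter = 0.5, outer_diameter = 30,
                            inner_samples = 16, outer_samples = 256) {
  stopifnot(inner_diameter > 0, inner_diameter < outer_diameter)
  structure(
    list(inner_diameter = inner_diameter, outer_diameter = outer_diameter,
         inner_samples = as.integer(inner_samples),
         outer_samples = as.integer(outer_samples)),
    class = "sampling_params"
  )
}

# disc sample coordinates for a set of centerline points: returns an
# (n_points * n_samples) x 3 matrix, grouped by point
disc_samples <- function(points, tangents, radius, n_samples) {
  pat <- disc_points_2d(n_samples, radius)
  out <- lapply(seq_len(nrow(points)), function(i) {
    basis <- plane_basis(tangents[i, ])
    sweep(pat %*% basis, 2, points[i, ], `+`)
  })
  do.call(rbind, out)
}

# Mean forward displacement over discs at several centerline points at once.
# Samples outside the model roi or the optional field of view are clipped;
# the retained fraction per disc is reported as coverage.
disc_means <- function(model, points, tangents, radius, n_samples, fov = NULL) {
  n <- nrow(points)
  S <- disc_samples(points, tangents, radius, n_samples)
  ok <- model$roi(S)
  if (!is.null(fov)) ok <- ok & in_fov(fov, S)
  disp <- matrix(0, nrow(S), 3)
  if (any(ok)) disp[ok, ] <- model$forward(S[ok, , drop = FALSE])
  grp <- rep(seq_len(n), each = n_samples)
  cnt <- as.vector(rowsum(as.numeric(ok), grp))
  sums <- rowsum(disp * ok, grp)
  mean_disp <- sums / pmax(cnt, 1)
  mean_disp[cnt == 0, ] <- NA_real_
  list(displacement = mean_disp, coverage = cnt / n_samples)
}

#' Mean displacement over a circular region of interest
#'
#' Area-normalised mean of the forward displacements over a disc of the
#' given diameter centred at `point`, oriented orthogonal to `tangent`.
#' Samples falling outside the model's trusted region (or the image field
#' of view) are clipped and the retained coverage fraction is reported;
#' coverage below 0.5 marks the measurement boundary-unreliable.
#'
#' @param model A [deformation_model].
#' @param point Centre, length-3 world mm.
#' @param tangent Local unit tangent.
#' @param diameter Disc diameter (mm).
#' @param n_samples Number of low-discrepancy sample points.
#' @param fov Optional [cine_volume()] supplying the field of view.
#' @return List with `displacement` (length 3, mm), `coverage`, `reliable`.
#' @export
disc_mean_displacement <- function(model, point, tangent, diameter,
                                   n_samples = 256, fov = NULL) {
  dm <- disc_means(model, matrix(point, 1, 3), matrix(tangent, 1, 3),
                   diameter / 2, n_samples, fov)
  list(displacement = drop(dm$displacement), coverage = dm$coverage,
       reliable = dm$coverage >= 0.5)
}

#' Common-mode-rejected local displacement at a centerline point
#'
#' Difference between the inner-disc and outer-disc mean displacements:
#' motion shared with the surroundings (breathing, cardiac, adjacent loops)
#' appears in both means and cancels; intraluminal motion survives.
#'
#' @inheritParams disc_mean_displacement
#' @param params A [sampling_params()].
#' @return List with `displacement` (length 3, mm), `reliable`,
#'   `coverage_inner`, `coverage_outer`.
#' @export
suppress_spurious <- function(model, point, tangent,
                              params = sampling_params(), fov = NULL) {
  inner <- disc_mean_displacement(model, point, tangent,
                                  params$inner_diameter,
                                  params$inner_samples, fov)
  outer <- disc_mean_displacement(model, point, tangent,
                                  params$outer_diameter,
                                  params$outer_samples, fov)
  list(
    displacement = inner$displacement - outer$displacement,
    reliable = inner$reliable && outer$reliable,
    coverage_inner = inner$coverage, coverage_outer = outer$coverage
  )
}

#' Signed local velocity along the centerline
#'
#' Projects a displacement vector onto the local unit tangent and divides by
#' the inter-frame interval, giving the velocity of intestinal content along
#' the direction of the intestine in mm/s. Negative values indicate motion
#' opposite to the centerline orientation.
#'
#' @param displacement n x 3 (or length-3) displacement in mm.
#' @param tangent Matching unit tangent(s).
#' @param dt Inter-frame interval in seconds (> 0).
#' @return Signed velocity (mm/s).
#' @export
local_velocity <- function(displacement, tangent, dt) {
  stopifnot(dt > 0)
  d <- matrix(as.numeric(displacement), ncol = 3)
  t <- matrix(as.numeric(tangent), ncol = 3)
  drop(rowSums(d * t) / dt)
}

#' Propagate a centerline through time
#'
#' The segment may drift over the acquisition (breathing, contractions in
#' neighbouring loops), so the centerline traced at the reference frame is
#' carried to every other frame. To avoid accumulating registration error,
#' each frame is related *directly* to the reference frame; the sampled
#' displacement vectors are smoothed with a centred moving average of 8 mm
#' along the centerline and 3 s across time before being added to the
#' reference points. At segment ends and at the first/last frame the
#' averaging window shrinks symmetrically, so boundary samples are never
#' biased towards one side (and the reference frame maps exactly to
#' itself).
#'
#' @param ref Reference [centerline] (resampled).
#' @param models_to_frames List of [deformation_model]s, one per frame,
#'   mapping reference-frame coordinates to that frame (the entry for the
#'   reference frame itself may be `NULL`, treated as identity).
#' @param spatial_window Moving-average window along arc length (mm).
#' @param temporal_window Moving-average window across time (s).
#' @param dt Inter-frame interval (s).
#' @return List with one point matrix (n x 3) per frame.
#' @export
propagate_centerline <- function(ref, models_to_frames,
                                 spatial_window = 8, temporal_window = 3,
                                 dt = 1.0) {
  P <- centerline_points(ref)
  n <- nrow(P)
  n_t <- length(models_to_frames)
  step <- attr(ref, "step")
  if (!is.numeric(step) || is.na(step)) step <- 1
  D <- array(0, c(n, 3, n_t))
  for (t in seq_len(n_t)) {
    m <- models_to_frames[[t]]
    if (is.null(m)) next
    if (!inherits(m, "deformation_model"))
      stop(sprintf("propagation error: missing model for frame %d", t - 1),
           call. = FALSE)
    D[, , t] <- m$forward(P)
  }
  hw_s <- floor(spatial_window / step / 2)
  for (t in seq_len(n_t))
    D[, , t] <- moving_average_rows(D[, , t], hw_s)
  hw_t <- floor(temporal_window / dt / 2)
  if (hw_t > 0 && n_t > 1) {
    for (i in seq_len(n)) {
      D[i, , ] <- t(moving_average_rows(t(D[i, , ]), hw_t))
    }
  }
  lapply(seq_len(n_t), function(t) P + D[, , t])
}

#' Space-time velocity map of an intestinal segment
#'
#' Runs the full motion-quantification chain for every consecutive frame
#' pair: deformable registration inside the 40 mm tube around the segment,
#' common-mode suppression at every propagated-centerline point, and
#' projection onto the local tangent. The result is a signed local velocity
#' (mm/s) indexed by arc-length position along the centerline and by frame
#' interval.
#'
#' Velocities are sampled at the propagated centerline of the earlier frame
#' of each pair, using that frame's local tangents.
#'
#' @param frames List of [cine_volume()]s (>= 2), in acquisition order.
#' @param centerline The segment [centerline], traced at the first frame of
#'   `frames`.
#' @param backend `"oracle"` (requires `truth`) or `"inr"` (trains the
#'   registration networks).
#' @param truth For the oracle backend: function `(X, from, to)` giving the
#'   ground-truth displacement between frame indices, e.g.
#'   `generate_phantom(...)$truth`.
#' @param params [registration_params()] for the `"inr"` backend.
#' @param sampling [sampling_params()].
#' @param tube_diameter Registration tube diameter (mm).
#' @param spatial_window,temporal_window Propagation smoothing windows
#'   (mm, s).
#' @return A `velocity_map` tibble with columns `position` (arc length, mm),
#'   `time` (s, start of the frame interval), `velocity` (mm/s) and
#'   `reliable` (boundary-reliability flag).
#' @export
compute_velocity_map <- function(frames, centerline,
                                 backend = c("oracle", "inr"),
                                 truth = NULL,
                                 params = registration_params("test"),
                                 sampling = sampling_params(),
                                 tube_diameter = 40,
                                 spatial_window = 8, temporal_window = 3) {
  backend <- match.arg(backend)
  n_t <- length(frames)
  if (n_t < 2) stop("need at least 2 frames", call. = FALSE)
  dt <- frames[[1]]$dt
  cl <- resample_centerline(centerline, step = attr(centerline, "step") %||% 1)
  if (!any(in_fov(frames[[1]], centerline_points(cl))))
    stop("centerline lies outside the image field of view", call. = FALSE)
  roi <- build_tube_roi(cl, tube_diameter)

  model_cache <- new.env(parent = emptyenv())
  get_model <- function(from, to) {
    key <- paste(from, to, sep = "_")
    if (!is.null(model_cache[[key]])) return(model_cache[[key]])
    m <- if (backend == "oracle") {
      if (is.null(truth))
        stop("oracle backend requires a `truth` displacement function",
             call. = FALSE)
      new_deformation_model(
        forward = function(X) truth(matrix(as.numeric(X), ncol = 3), from, to),
        backward = function(X) truth(matrix(as.numeric(X), ncol = 3), to, from),
        roi = function(X) rep(TRUE, nrow(matrix(as.numeric(X), ncol = 3))),
        diagnostics = list(backend = "oracle")
      )
    } else {
      p <- params
      p$seed <- params$seed + 1000L * from + to
      tryCatch(
        register_pair(frames[[from + 1]], frames[[to + 1]], roi, p),
        error = function(e) stop(sprintf(
          "registration failed for frame pair %d -> %d: %s",
          from, to, conditionMessage(e)), call. = FALSE)
      )
    }
    model_cache[[key]] <- m
    m
  }

  ref <- attr(cl, "frame_index") %||% 0L
  to_frames <- lapply(seq_len(n_t) - 1L, function(t) {
    if (t == ref) NULL else get_model(ref, t)
  })
  lines <- propagate_centerline(cl, to_frames, spatial_window,
                                temporal_window, dt)

  arc <- cl$arc_length
  rows <- vector("list", n_t - 1)
  for (k in seq_len(n_t - 1)) {
    mdl <- get_model(k - 1L, k)
    P <- lines[[k]]
    tang <- polyline_tangents(P)
    inner <- disc_means(mdl, P, tang, sampling$inner_diameter / 2,
                        sampling$inner_samples, frames[[k]])
    outer <- disc_means(mdl, P, tang, sampling$outer_diameter / 2,
                        sampling$outer_samples, frames[[k]])
    disp <- inner$displacement - outer$displacement
    vel <- local_velocity(disp, tang, dt)
    rows[[k]] <- tibble::tibble(
      position = arc,
      time = (k - 1) * dt,
      velocity = vel,
      reliable = inner$coverage >= 0.5 & outer$coverage >= 0.5
    )
  }
  map <- dplyr::bind_rows(rows)
  attr(map, "dt") <- dt
  attr(map, "segment_length") <- segment_length(cl)
  attr(map, "n_positions") <- length(arc)
  attr(map, "n_intervals") <- n_t - 1L
  attr(map, "diagnostics") <- lapply(
    ls(model_cache), function(k) model_cache[[k]]$diagnostics
  )
  class(map) <- c("velocity_map", class(map))
  map
}

#' Reverse the orientation of a velocity map
#'
#' Flipping the (arbitrary) centerline orientation negates every signed
#' velocity and mirrors the arc-length positions; the magnitude of motility
#' is unchanged.
#'
#' @param map A `velocity_map`.
#' @return The flipped `velocity_map`.
#' @export
flip_orientation <- function(map) {
  L <- attr(map, "segment_length") %||% max(map$position)
  map$velocity <- -map$velocity
  map$position <- L - map$position
  map
}

#' Aggregate a velocity map into segment-level motility metrics
#'
#' Two global metrics summarise a segment: the *mean velocity* (grand mean
#' of the signed local velocities over positions and time; opposing motion
#' cancels, so only consistent peristalsis yields large values) and the
#' *mean absolute velocity* (absolute values taken before averaging; large
#' for any vigorous motion including uncoordinated mixing). For
#' visualisation, per-interval averages over the first, middle and final
#' thirds of the arc length are also returned.
#'
#' @param map A `velocity_map`.
#' @param exclude_unreliable Drop boundary-unreliable samples before
#'   aggregating (default keeps them).
#' @return A one-row `segment_metrics` tibble with columns `mean_velocity`
#'   and `mean_absolute_velocity` (mm/s); the per-third per-interval means
#'   are in `attr(, "three_part")` (see [three_part_means()]).
#' @export
aggregate_metrics <- function(map, exclude_unreliable = FALSE) {
  if (nrow(map) == 0) stop("empty velocity map", call. = FALSE)
  m <- map
  if (exclude_unreliable) m <- m[m$reliable, , drop = FALSE]
  if (nrow(m) == 0) stop("no reliable samples in velocity map", call. = FALSE)
  L <- attr(map, "segment_length") %||% max(map$position)
  part <- cut(m$position, breaks = c(-Inf, L / 3, 2 * L / 3, Inf),
              labels = c("begin", "middle", "end"))
  three <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(time = m$time, part = part,
                                   velocity = m$velocity),
                    .data$time, .data$part),
    velocity = mean(.data$velocity), .groups = "drop"
  )
  out <- tibble::tibble(
    mean_velocity = mean(m$velocity),
    mean_absolute_velocity = mean(abs(m$velocity)),
    n_samples = nrow(m)
  )
  attr(out, "three_part") <- three
  class(out) <- c("segment_metrics", class(out))
  out
}

#' Per-third average velocities of a segment
#'
#' @param metrics A `segment_metrics` object from [aggregate_metrics()].
#' @return Tibble with columns `time`, `part` (begin/middle/end),
#'   `velocity`.
#' @export
three_part_means <- function(metrics) {
  attr(metrics, "three_part")
}
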