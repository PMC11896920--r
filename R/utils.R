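# Internal numerical utilities shared across modules.

#' @importFrom stats rnorm runif setNames approx median quantile sd
#' @importFrom utils head tail
NULL

# Evaluate a scalar 3D grid at arbitrary world coordinates by trilinear
# interpolation. Coordinates outside the grid are clamped to the boundary
# (constant extrapolation). `vol` is a 3D array; `origin` is the world
# position of voxel (1,1,1); `xyz` is an n x 3 matrix in mm.
interp_trilinear <- function(vol, origin, spacing, xyz) {
  d <- dim(vol)
  n <- nrow(xyz)
  out <- numeric(n)
  # continuous 0-based voxel index
  ix <- (xyz[, 1] - origin[1]) / spacing[1]
  iy <- (xyz[, 2] - origin[2]) / spacing[2]
  iz <- (xyz[, 3] - origin[3]) / spacing[3]
  ix <- pmin(pmax(ix, 0), d[1] - 1)
  iy <- pmin(pmax(iy, 0), d[2] - 1)
  iz <- pmin(pmax(iz, 0), d[3] - 1)
  x0 <- pmin(floor(ix), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(iy), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(iz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, n)
  if (d[2] == 1) y0 <- rep(0, n)
  if (d[3] == 1) z0 <- rep(0, n)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  # flattened 1-based indices of the 8 corners
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  base <- 1 + x0 * sx + y0 * sy + z0 * sz
  dx <- if (d[1] > 1) sx else 0L
  dy <- if (d[2] > 1) sy else 0L
  dz <- if (d[3] > 1) sz else 0L
  v000 <- vol[base]
  v100 <- vol[base + dx]
  v010 <- vol[base + dy]
  v110 <- vol[base + dx + dy]
  v001 <- vol[base + dz]
  v101 <- vol[base + dx + dz]
  v011 <- vol[base + dy + dz]
  v111 <- vol[base + dx + dy + dz]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Central-difference gradient volumes of a 3D array, in units per mm.
gradient_volumes <- function(vol, spacing) {
  d <- dim(vol)
  shift <- function(axis, by) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
    idx[[axis]] <- i
    do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
  }
  lapply(1:3, function(ax) {
    if (d[ax] < 2) return(array(0, d))
    (shift(ax, 1L) - shift(ax, -1L)) / (2 * spacing[ax])
  })
}

# Deterministic quasi-uniform points on a disc of given radius (mm) centred
# at the origin of its own plane: sunflower (Fibonacci) spiral.
disc_points_2d <- function(n, radius) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- radius * sqrt((i - 0.5) / n)
  th <- i * golden
  cbind(r * cos(th), r * sin(th))
}

# Orthonormal basis of the plane orthogonal to a tangent. The basis depends
# only on the tangent *line* (the sign of the tangent is canonicalised), so
# reversing a centerline's orientation leaves every sampling disc unchanged.
plane_basis <- function(tangent) {
  t <- tangent / sqrt(sum(tangent^2))
  flip <- t[1] < 0 || (t[1] == 0 && (t[2] < 0 || (t[2] == 0 && t[3] < 0)))
  if (flip) t <- -t
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * t) * t
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    t[2] * e1[3] - t[3] * e1[2],
    t[3] * e1[1] - t[1] * e1[3],
    t[1] * e1[2] - t[2] * e1[1]
  )
  rbind(e1, e2)
}

# Centred moving average along the rows of a matrix (one column per
# component). At the ends the window shrinks symmetrically, so it stays
# centred on the sample (the first and last samples pass through
# unchanged).
moving_average_rows <- function(m, halfwidth) {
  if (halfwidth <= 0) return(m)
  n <- nrow(m)
  cs <- apply(rbind(0, m), 2, cumsum)
  i <- seq_len(n)
  hw <- pmin(halfwidth, i - 1L, n - i)
  lo <- i - hw
  hi <- i + hw
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# round-half-up to integer percent, matching clinical reporting style
percent_round <- function(x) floor(100 * x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
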