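test_that("a uniform field passes through disc means unchanged", {
  c0 <- c(1.2, -0.7, 3.1)
  mdl <- field_model(function(X) matrix(c0, nrow(X), 3, byrow = TRUE))
  for (diam in c(0.5, 30)) {
    r <- disc_mean_displacement(mdl, c(10, 10, 10), c(1, 0, 0), diam)
    expect_equal(r$displacement, c0, tolerance = 1e-12)
    expect_equal(r$coverage, 1)
  }
})

test_that("an odd linear field averages to ~0 over a centred disc", {
  mdl <- field_model(function(X) cbind(X[, 2], 0 * X[, 2], 0 * X[, 2]))
  r <- disc_mean_displacement(mdl, c(0, 0, 0), c(1, 0, 0), 30)
  # the sunflower pattern is balanced to ~1% of the disc radius
  expect_lt(abs(r$displacement[1]), 0.15)
})

test_that("a lumen-confined field is diluted by the outer-disc area fraction", {
  v <- 2
  lumen_field <- function(X) {
    r <- sqrt(X[, 2]^2 + X[, 3]^2)  # distance from the x-axis
    cbind(v * (r < 5), 0 * r, 0 * r)
  }
  mdl <- field_model(lumen_field)
  r <- disc_mean_displacement(mdl, c(0, 0, 0), c(1, 0, 0), 30)
  # brute-force Monte-Carlo oracle for the same mean
  set.seed(42)
  n <- 2e5
  rad <- 15 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  mc <- mean(lumen_field(cbind(0, rad * cos(th), rad * sin(th)))[, 1])
  expect_equal(mc, v * (5 / 15)^2, tolerance = 0.01)
  expect_equal(r$displacement[1], v * (5 / 15)^2, tolerance = 0.02 * v)
})

test_that("suppression rejects uniform translation exactly", {
  c0 <- c(0.8, -1.4, 2.2)
  mdl <- field_model(function(X) matrix(c0, nrow(X), 3, byrow = TRUE))
  s <- suppress_spurious(mdl, c(12, 7, 3), c(0, 1, 0))
  expect_lt(max(abs(s$displacement)), 1e-12)
  expect_true(s$reliable)
})

test_that("suppression keeps (8/9) of a 5 mm lumen field and ignores an added translation", {
  v <- 2
  base <- function(X) {
    r <- sqrt(X[, 2]^2 + X[, 3]^2)
    cbind(v * (r < 5), 0 * r, 0 * r)
  }
  with_cm <- function(X) base(X) + matrix(c(3, -1, 2), nrow(X), 3, byrow = TRUE)
  s1 <- suppress_spurious(field_model(base), c(0, 0, 0), c(1, 0, 0))
  s2 <- suppress_spurious(field_model(with_cm), c(0, 0, 0), c(1, 0, 0))
  expect_equal(s1$displacement[1], v * 8 / 9, tolerance = 0.05 * v)
  expect_equal(s1$displacement, s2$displacement, tolerance = 1e-12)
})

test_that("suppression is exactly invariant to adding any uniform field", {
  f <- function(X) cbind(sin(X[, 1] / 4), cos(X[, 2] / 6), 0 * X[, 3])
  g <- function(X) f(X) + matrix(c(-2.3, 0.9, 4.1), nrow(X), 3, byrow = TRUE)
  s1 <- suppress_spurious(field_model(f), c(5, 5, 5), c(0, 0, 1))
  s2 <- suppress_spurious(field_model(g), c(5, 5, 5), c(0, 0, 1))
  expect_equal(s1$displacement, s2$displacement, tolerance = 1e-12)
})

test_that("low coverage raises the boundary-unreliable flag", {
  half_roi <- function(X) X[, 2] > 1  # cuts away most of the outer disc
  mdl <- oracle_backend(function(X) 0 * X, function(X) 0 * X, roi = half_roi)
  s <- suppress_spurious(mdl, c(0, 0, 0), c(1, 0, 0))
  expect_false(s$reliable)
  expect_lt(s$coverage_outer, 0.5)
})

test_that("local velocity is the tangential component over dt", {
  expect_equal(local_velocity(c(1.4, 0, 0), c(1, 0, 0), 1), 1.4)
  expect_equal(local_velocity(c(0, 2, 0), c(1, 0, 0), 1), 0)
  expect_equal(local_velocity(c(1, 1, 0), c(sqrt(2) / 2, sqrt(2) / 2, 0), 1),
               sqrt(2), tolerance = 1e-12)
  expect_equal(local_velocity(c(2, 0, 0), c(1, 0, 0), 2), 1)
})

test_that("propagation under identity and constant-translation models", {
  cl <- resample_centerline(cbind(c(5, 50), 20, 10), step = 1)
  idm <- oracle_backend(function(X) 0 * X, function(X) 0 * X)
  lines <- propagate_centerline(cl, list(NULL, idm, idm))
  for (t in 1:3)
    expect_equal(lines[[t]], centerline_points_mat(cl), tolerance = 1e-12)

  # a scene translating rigidly by c0 at every frame (reference included)
  c0 <- c(2, -1, 0.5)
  cm <- oracle_backend(function(X) matrix(c0, nrow(X), 3, byrow = TRUE),
                       function(X) matrix(-c0, nrow(X), 3, byrow = TRUE))
  lines2 <- propagate_centerline(cl, list(cm, cm, cm))
  expect_equal(lines2[[2]],
               sweep(centerline_points_mat(cl), 2, c0, `+`),
               tolerance = 1e-12)
})

test_that("propagation tracks a slow breathing phantom within 0.5 mm RMS", {
  cfg <- phantom_config(
    grid_shape = small_grid, n_frames = 6, lumen_radius = 5,
    common_mode = function(t) 3 * sin(2 * pi * t / 12) * c(1, 1, 0) / sqrt(2),
    seed = 2
  )
  ph <- generate_phantom(cfg)
  models <- lapply(0:5, function(t) {
    if (t == 0) return(NULL)
    oracle_backend(function(X) ph$truth(X, 0, t),
                   function(X) ph$truth(X, t, 0))
  })
  lines <- propagate_centerline(ph$centerline, models)
  P <- centerline_points_mat(ph$centerline)
  for (t in 1:6) {
    tru <- P + ph$truth(P, 0, t - 1)
    expect_lt(sqrt(mean(rowSums((lines[[t]] - tru)^2))), 0.5)
  }
})

test_that("missing frame models abort propagation", {
  cl <- resample_centerline(cbind(c(5, 50), 20, 10), step = 1)
  expect_error(propagate_centerline(cl, list(NULL, "not a model")),
               "propagation error")
})

test_that("oracle velocity maps recover the prescribed flow pattern", {
  m_fwd <- aggregate_metrics(small_oracle_map("motile_forward"))
  expect_equal(m_fwd$mean_velocity, 2, tolerance = 0.15)
  m_non <- aggregate_metrics(small_oracle_map("non_motile"))
  expect_lt(m_non$mean_absolute_velocity, 0.15)
})

test_that("reversing the centerline negates the map exactly", {
  ph <- small_phantom("motile_forward")
  cl <- resample_centerline(ph$centerline, 1)
  map <- small_oracle_map("motile_forward")
  rev_pts <- centerline_points_mat(cl)[nrow(cl):1, ]
  map_rev <- compute_velocity_map(ph$frames,
                                  resample_centerline(rev_pts, 1),
                                  backend = "oracle", truth = ph$truth)
  m <- aggregate_metrics(map)
  mr <- aggregate_metrics(map_rev)
  expect_equal(mr$mean_velocity, -m$mean_velocity)
  expect_equal(mr$mean_absolute_velocity, m$mean_absolute_velocity)
  # position-wise: values mirrored and negated
  L <- segment_length(cl)
  key <- function(mp) mp[order(mp$time, round(mp$position, 6)), ]
  flipped <- map_rev
  flipped$position <- L - flipped$position
  flipped$velocity <- -flipped$velocity
  expect_equal(key(flipped)$velocity, key(map)$velocity)
})

test_that("metrics equal a brute-force recomputation on random maps", {
  set.seed(11)
  for (rep in 1:5) {
    n_pos <- sample(10:40, 1); n_t <- sample(2:6, 1)
    map <- tibble::tibble(
      position = rep(seq(0, n_pos - 1), times = n_t),
      time = rep(seq_len(n_t) - 1, each = n_pos),
      velocity = rnorm(n_pos * n_t, sd = 2),
      reliable = TRUE
    )
    attr(map, "segment_length") <- n_pos - 1
    class(map) <- c("velocity_map", class(map))
    m <- aggregate_metrics(map)
    expect_identical(m$mean_velocity, mean(map$velocity))
    expect_identical(m$mean_absolute_velocity, mean(abs(map$velocity)))
    expect_true(abs(m$mean_velocity) <= m$mean_absolute_velocity)
    # three-part oracle: direct re-summation by thirds
    L <- n_pos - 1
    grp <- 1 + (map$position > L / 3) + (map$position > 2 * L / 3)
    oracle <- tapply(map$velocity, list(map$time, grp), mean)
    three <- three_part_means(m)
    for (t in unique(map$time)) {
      for (g in 1:3) {
        got <- three$velocity[three$time == t &
                                three$part == c("begin", "middle", "end")[g]]
        expect_equal(got, unname(oracle[as.character(t), g]))
      }
    }
  }
})

test_that("constant and half-split maps give the stated metric pairs", {
  mk <- function(vel) {
    map <- tibble::tibble(position = seq_along(vel) - 1, time = 0,
                          velocity = vel, reliable = TRUE)
    class(map) <- c("velocity_map", class(map))
    map
  }
  m1 <- aggregate_metrics(mk(rep(1.5, 30)))
  expect_equal(m1$mean_velocity, 1.5)
  expect_equal(m1$mean_absolute_velocity, 1.5)
  m2 <- aggregate_metrics(mk(c(rep(2, 15), rep(-2, 15))))
  expect_equal(m2$mean_velocity, 0)
  expect_equal(m2$mean_absolute_velocity, 2)
  expect_error(aggregate_metrics(mk(numeric(0))), "empty")
})

test_that("flip_orientation negates velocities and mirrors positions", {
  map <- small_oracle_map("motile_forward")
  fl <- flip_orientation(map)
  m <- aggregate_metrics(map); mf <- aggregate_metrics(fl)
  expect_identical(mf$mean_velocity, -m$mean_velocity)
  expect_identical(mf$mean_absolute_velocity, m$mean_absolute_velocity)
})
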