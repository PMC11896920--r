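# Shared fixtures, built lazily once per test run and cached, so expensive
# objects (phantoms, trained registrations) are not recomputed per test.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]]))
    assign(name, force(expr), envir = .fixture_env)
  .fixture_env[[name]]
}

# compact geometry used throughout: >40 mm segment, 5 mm lumen, fast
small_grid <- c(48, 48, 10)

small_phantom <- function(kind, seed = 4, n_frames = 4, ...) {
  fixture(paste("ph", kind, seed, n_frames, sep = "_"), {
    generate_phantom(preset_phantom(
      kind, seed = seed, grid_shape = small_grid,
      n_frames = n_frames, lumen_radius = 5, ...
    ))
  })
}

small_oracle_map <- function(kind, seed = 4, n_frames = 4) {
  fixture(paste("map", kind, seed, n_frames, sep = "_"), {
    ph <- small_phantom(kind, seed, n_frames)
    compute_velocity_map(ph$frames, ph$centerline,
                         backend = "oracle", truth = ph$truth)
  })
}

# phantom pair related by a pure 2-voxel translation, plus its trained
# registration (test profile); reused by several registration tests
translation_fixture <- function() {
  fixture("translation", {
    cfg <- phantom_config(
      grid_shape = c(64, 64, 12), n_frames = 2, lumen_radius = 6,
      noise_sd = 0, common_mode = function(t) c(2.8, 0, 0) * t, seed = 11
    )
    ph <- generate_phantom(cfg)
    roi <- build_tube_roi(ph$centerline, 40)
    model <- register_pair(ph$frames[[1]], ph$frames[[2]], roi,
                           registration_params("test", seed = 1))
    vox <- voxel_coordinates(ph$frames[[1]])
    vox <- vox[roi$indicator(vox), , drop = FALSE]
    probe <- vox[round(seq(1, nrow(vox), length.out = 500)), , drop = FALSE]
    list(phantom = ph, roi = roi, model = model, probe = probe)
  })
}

synthetic_cohort <- function() {
  fixture("cohort", synthetic_segment_table(n_per_class = 10, seed = 1))
}

# deformation model from an analytic displacement field (trusted everywhere)
field_model <- function(forward, backward = NULL) {
  oracle_backend(forward, backward)
}

centerline_points_mat <- function(cl) unname(as.matrix(cl[, c("x", "y", "z")]))

# half-up rounding to integer percent, as used in clinical reporting
percent_round_ <- function(x) floor(100 * x + 0.5)

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}
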