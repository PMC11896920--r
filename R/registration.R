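#' Deformation models
#'
#' A deformation model is a bidirectional continuous mapping between two
#' time points, queryable at arbitrary world coordinates (mm): `forward(X)`
#' returns the n x 3 displacement taking frame-A points to frame B, and
#' `backward(X)` the reverse. `roi(X)` indicates where the model is trusted.
#' `diagnostics` carries the final loss terms, iteration count and the cycle
#' residual `|backward(x + forward(x)) + forward(x)|` measured on a fixed
#' probe grid.
#'
#' @name deformation_model
NULL

new_deformation_model <- function(forward, backward, roi, diagnostics = list()) {
  structure(
    list(forward = forward, backward = backward, roi = roi,
         diagnostics = diagnostics),
    class = "deformation_model"
  )
}

#' @export
print.deformation_model <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<deformation_model> backend %s%s\n",
    d$backend %||% "?",
    if (!is.null(d$cycle_residual))
      sprintf(", cycle residual %.2e mm", d$cycle_residual) else ""
  ))
  invisible(x)
}

# minimum distance from each row of X to a polyline given by `pts`
dist_to_polyline <- function(X, pts) {
  n <- nrow(X)
  best <- rep(Inf, n)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; ab <- pts[i + 1, ] - a
    len2 <- sum(ab^2)
    rel <- sweep(X, 2, a)
    t <- if (len2 > 0) pmin(pmax((rel %*% ab) / len2, 0), 1) else 0
    dx <- rel[, 1] - t * ab[1]
    dy <- rel[, 2] - t * ab[2]
    dz <- rel[, 3] - t * ab[3]
    best <- pmin(best, dx^2 + dy^2 + dz^2)
  }
  sqrt(best)
}

#' Tubular region of interest around a centerline
#'
#' The motion field is only estimated inside a tube around the segment
#' centerline. The default diameter of 40 mm exceeds any healthy or mildly
#' distended small intestine (20-30 mm) and can be expanded by the user for
#' severely distended segments.
#'
#' @param centerline A [centerline].
#' @param diameter Tube diameter in mm (> 0).
#' @return A `tube_roi` object: an indicator over world coordinates plus the
#'   generating geometry.
#' @export
build_tube_roi <- function(centerline, diameter = 40) {
  stopifnot(diameter > 0)
  pts <- coerce_points(centerline)
  radius <- diameter / 2
  indicator <- function(X) {
    X <- matrix(as.numeric(X), ncol = 3)
    dist_to_polyline(X, pts) <= radius
  }
  structure(
    list(indicator = indicator, points = pts, diameter = diameter,
         bbox = rbind(apply(pts, 2, min) - radius, apply(pts, 2, max) + radius)),
    class = "tube_roi"
  )
}

#' Registration parameters
#'
#' Settings for the implicit-neural-representation registration backend.
#' The `"full"` profile mirrors the reference optimisation schedule (1500
#' iterations, one-cycle learning-rate policy, 3 x 256 SIREN); the `"test"`
#' profile (300 iterations, width 64, smaller batches) is for desk-scale
#' runs and continuous testing.
#'
#' @param profile `"full"` or `"test"` baseline, fields overridable below.
#' @param iterations Optimisation steps (>= 1).
#' @param batch_size Coordinates sampled per iteration.
#' @param width,hidden_layers,omega0 SIREN architecture: hidden width, number
#'   of hidden layers, sinusoidal frequency scale.
#' @param max_lr,warmup One-cycle schedule: peak learning rate (1e-4 for the
#'   full profile; 5e-4 for the short test profile, whose 5x fewer steps need
#'   a proportionally larger step size to traverse the same distance) and
#'   warm-up fraction.
#' @param w_ncc,w_jacobian,w_cycle Loss weights (>= 0) for the normalized
#'   cross-correlation term, the symmetric Jacobian-determinant penalty and
#'   the cycle-consistency penalty.
#' @param jacobian_subsample Points per iteration used for the Jacobian
#'   penalty (finite differences of the displacement field).
#' @param fd_step Finite-difference step (mm) for the Jacobian penalty.
#' @param disp_scale Output scale (mm): network outputs are multiplied by
#'   this factor to produce displacements.
#' @param probe_points Size of the fixed probe grid on which the cycle
#'   residual diagnostic is reported.
#' @param seed Integer seed; registration is deterministic given the seed.
#' @return A `registration_params` list.
#' @export
registration_params <- function(profile = c("full", "test"),
                                iterations = NULL, batch_size = NULL,
                                width = NULL, hidden_layers = 3, omega0 = 30,
                                max_lr = NULL, warmup = 0.1,
                                w_ncc = 1.0, w_jacobian = 0.05, w_cycle = 1.0,
                                jacobian_subsample = 64, fd_step = 0.5,
                                disp_scale = 10, probe_points = 200,
                                seed = 1L) {
  profile <- match.arg(profile)
  base <- switch(profile,
    full = list(iterations = 1500, batch_size = 1000, width = 256,
                max_lr = 1e-4),
    test = list(iterations = 300, batch_size = 512, width = 64,
                max_lr = 5e-4)
  )
  p <- list(
    profile = profile,
    iterations = iterations %||% base$iterations,
    batch_size = batch_size %||% base$batch_size,
    width = width %||% base$width,
    hidden_layers = hidden_layers, omega0 = omega0,
    max_lr = max_lr %||% base$max_lr, warmup = warmup,
    w_ncc = w_ncc, w_jacobian = w_jacobian, w_cycle = w_cycle,
    jacobian_subsample = jacobian_subsample, fd_step = fd_step,
    disp_scale = disp_scale, probe_points = probe_points,
    seed = as.integer(seed)
  )
  stopifnot(p$iterations >= 1, w_ncc >= 0, w_jacobian >= 0, w_cycle >= 0)
  class(p) <- "registration_params"
  p
}

# NCC between a fixed and a moving intensity vector, with the gradient of
# NCC with respect to the moving intensities.
ncc_with_grad <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  Saa <- sum(ac^2); Sbb <- sum(bc^2)
  if (Saa < 1e-12 || Sbb < 1e-12)
    return(list(ncc = 0, db = numeric(length(b))))
  Sab <- sum(ac * bc)
  den <- sqrt(Saa * Sbb)
  ncc <- Sab / den
  db <- (ac - ncc * sqrt(Saa / Sbb) * bc) / den
  # centring of b contributes nothing extra: sum(db) is already 0
  list(ncc = ncc, db = db)
}

# determinants of I + dD/dx from a stacked finite-difference evaluation;
# D_plus/D_minus are (m*3) x 3 matrices of displacements at x + h e_q,
# grouped by axis q. Returns dets and (optionally) the upstream gradients.
fd_jacobian <- function(D_plus, D_minus, m, h) {
  J <- array(0, c(m, 3, 3))
  for (q in 1:3) {
    rows <- ((q - 1) * m + 1):(q * m)
    J[, , q] <- (D_plus[rows, , drop = FALSE] - D_minus[rows, , drop = FALSE]) / (2 * h)
  }
  for (p in 1:3) J[, p, p] <- J[, p, p] + 1
  det3 <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  list(J = J, det = det3)
}

# adjugate-transpose of each 3x3 slice: d(det)/dJ
adjugate_t <- function(J) {
  m <- dim(J)[1]
  G <- array(0, c(m, 3, 3))
  G[, 1, 1] <- J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]
  G[, 1, 2] <- -(J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1])
  G[, 1, 3] <- J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]
  G[, 2, 1] <- -(J[, 1, 2] * J[, 3, 3] - J[, 1, 3] * J[, 3, 2])
  G[, 2, 2] <- J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]
  G[, 2, 3] <- -(J[, 1, 1] * J[, 3, 2] - J[, 1, 2] * J[, 3, 1])
  G[, 3, 1] <- J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]
  G[, 3, 2] <- -(J[, 1, 1] * J[, 2, 3] - J[, 1, 3] * J[, 2, 1])
  G[, 3, 3] <- J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
  G
}

#' Register two cine frames inside a tubular region of interest
#'
#' Jointly optimises two sinusoidal coordinate networks representing the
#' forward (A to B) and backward (B to A) displacement fields, under a
#' composite objective: normalized cross-correlation of the mapped
#' intensities in both directions, a symmetric Jacobian-determinant penalty
#' (squared log-determinant of either map, discouraging folding and extreme
#' volume change), and a cycle-consistency penalty (mean squared residual of
#' composing the two maps). Coordinates are sampled uniformly from the
#' voxel centres inside the region of interest and normalised to
#' \[-1, 1\] over its bounding box.
#'
#' @param vol_a,vol_b Two [cine_volume()] objects on the same grid.
#' @param roi A [build_tube_roi()] region (or any object with an
#'   `indicator` function).
#' @param params [registration_params()].
#' @return A [deformation_model].
#' @export
register_pair <- function(vol_a, vol_b, roi, params = registration_params("full")) {
  if (!isTRUE(all.equal(dim(vol_a$voxels), dim(vol_b$voxels))) ||
      !isTRUE(all.equal(vol_a$spacing, vol_b$spacing)))
    stop("volumes must share grid and spacing", call. = FALSE)
  coords <- voxel_coordinates(vol_a)
  inside <- roi$indicator(coords)
  if (!any(inside))
    stop("roi error: region of interest does not intersect the image",
         call. = FALSE)
  coords <- coords[inside, , drop = FALSE]
  n_cand <- nrow(coords)

  ctr <- (apply(coords, 2, max) + apply(coords, 2, min)) / 2
  half <- pmax((apply(coords, 2, max) - apply(coords, 2, min)) / 2, 1e-6)
  norm_x <- function(X) sweep(sweep(X, 2, ctr), 2, half, `/`)

  a_all <- sample_volume(vol_a, coords)
  b_all <- sample_volume(vol_b, coords)
  ga <- gradient_volumes(vol_a$voxels, vol_a$spacing)
  gb <- gradient_volumes(vol_b$voxels, vol_b$spacing)
  grad_at <- function(gv, vol, X) {
    cbind(
      interp_trilinear(gv[[1]], vol$origin, vol$spacing, X),
      interp_trilinear(gv[[2]], vol$origin, vol$spacing, X),
      interp_trilinear(gv[[3]], vol$origin, vol$spacing, X)
    )
  }

  p <- params
  batch <- min(p$batch_size, n_cand)
  m <- min(p$jacobian_subsample, batch)
  h <- p$fd_step
  scale <- p$disp_scale
  probe_idx <- unique(round(seq(1, n_cand, length.out = min(p$probe_points, n_cand))))
  probe <- coords[probe_idx, , drop = FALSE]

  fit <- with_local_seed(p$seed, {
    netF <- siren_init(width = p$width, hidden_layers = p$hidden_layers,
                       omega0 = p$omega0)
    netG <- siren_init(width = p$width, hidden_layers = p$hidden_layers,
                       omega0 = p$omega0)
    optF <- adam_init(netF); optG <- adam_init(netG)

    eval_disp <- function(net, X) scale * siren_forward(net, norm_x(X))$out

    cycle_probe <- function() {
      dF <- eval_disp(netF, probe)
      dG <- eval_disp(netG, probe + dF)
      mean(sqrt(rowSums((dG + dF)^2)))
    }
    initial_cycle <- cycle_probe()

    history <- list()
    for (it in seq_len(p$iterations)) {
      lr <- one_cycle_lr(it, p$iterations, p$max_lr, p$warmup)
      idx <- sample.int(n_cand, batch)
      X <- coords[idx, , drop = FALSE]
      Xn <- norm_x(X)
      a_fix <- a_all[idx]; b_fix <- b_all[idx]

      fF <- siren_forward(netF, Xn); dispF <- scale * fF$out
      fG <- siren_forward(netG, Xn); dispG <- scale * fG$out
      YF <- X + dispF; YG <- X + dispG

      # --- NCC terms (both directions) ---
      b_mov <- sample_volume(vol_b, YF)
      a_mov <- sample_volume(vol_a, YG)
      nF <- ncc_with_grad(a_fix, b_mov)
      nG <- ncc_with_grad(b_fix, a_mov)
      gB <- grad_at(gb, vol_b, YF)
      gA <- grad_at(ga, vol_a, YG)
      dDispF <- (-p$w_ncc / 2) * nF$db * gB
      dDispG <- (-p$w_ncc / 2) * nG$db * gA

      # --- cycle-consistency (both directions) ---
      YFn <- norm_x(YF); YGn <- norm_x(YG)
      fGy <- siren_forward(netG, YFn)
      fFy <- siren_forward(netF, YGn)
      CF <- scale * fGy$out + dispF
      CG <- scale * fFy$out + dispG
      cycF <- sum(CF^2) / batch
      cycG <- sum(CG^2) / batch
      dCF <- (p$w_cycle / 2) * 2 * CF / batch
      dCG <- (p$w_cycle / 2) * 2 * CG / batch
      bGy <- siren_backward(netG, fGy, dCF * scale)
      bFy <- siren_backward(netF, fFy, dCG * scale)
      dDispF <- dDispF + dCF + sweep(bGy$dX, 2, half, `/`)
      dDispG <- dDispG + dCG + sweep(bFy$dX, 2, half, `/`)

      # --- symmetric Jacobian penalty (finite differences on a subsample) ---
      Xj <- X[seq_len(m), , drop = FALSE]
      stack_pts <- function(sign) {
        rbind(
          Xj + matrix(c(sign * h, 0, 0), m, 3, byrow = TRUE),
          Xj + matrix(c(0, sign * h, 0), m, 3, byrow = TRUE),
          Xj + matrix(c(0, 0, sign * h), m, 3, byrow = TRUE)
        )
      }
      Xp <- stack_pts(1); Xm <- stack_pts(-1)
      jac_term <- function(net) {
        fp <- siren_forward(net, norm_x(Xp))
        fm <- siren_forward(net, norm_x(Xm))
        fd <- fd_jacobian(scale * fp$out, scale * fm$out, m, h)
        det_c <- pmax(fd$det, 1e-6)
        logd <- log(det_c)
        pen <- mean(logd^2)
        Gm <- adjugate_t(fd$J)
        coef <- ifelse(fd$det > 1e-6, 2 * logd / det_c, 0) / m
        dJ <- Gm * coef  # broadcast over slices
        dOutP <- matrix(0, 3 * m, 3); dOutM <- matrix(0, 3 * m, 3)
        for (q in 1:3) {
          rows <- ((q - 1) * m + 1):(q * m)
          dOutP[rows, ] <- dJ[, , q] / (2 * h)
          dOutM[rows, ] <- -dJ[, , q] / (2 * h)
        }
        list(pen = pen, fp = fp, fm = fm, dOutP = dOutP, dOutM = dOutM)
      }
      jF <- jac_term(netF)
      jG <- jac_term(netG)

      loss <- -p$w_ncc * (nF$ncc + nG$ncc) / 2 +
        p$w_cycle * (cycF + cycG) / 2 +
        p$w_jacobian * (jF$pen + jG$pen) / 2
      if (!is.finite(loss))
        stop(sprintf(
          "optimization diverged at iteration %d (ncc %.3g/%.3g cycle %.3g/%.3g jac %.3g/%.3g)",
          it, nF$ncc, nG$ncc, cycF, cycG, jF$pen, jG$pen), call. = FALSE)

      # --- accumulate parameter gradients and update ---
      add_grads <- function(g1, g2) {
        list(gW = Map(`+`, g1$gW, g2$gW), gb = Map(`+`, g1$gb, g2$gb))
      }
      bF <- siren_backward(netF, fF, dDispF * scale)
      bG <- siren_backward(netG, fG, dDispG * scale)
      bFj_p <- siren_backward(netF, jF$fp, (p$w_jacobian / 2) * jF$dOutP * scale)
      bFj_m <- siren_backward(netF, jF$fm, (p$w_jacobian / 2) * jF$dOutM * scale)
      bGj_p <- siren_backward(netG, jG$fp, (p$w_jacobian / 2) * jG$dOutP * scale)
      bGj_m <- siren_backward(netG, jG$fm, (p$w_jacobian / 2) * jG$dOutM * scale)
      gradF <- add_grads(add_grads(bF, bFy), add_grads(bFj_p, bFj_m))
      gradG <- add_grads(add_grads(bG, bGy), add_grads(bGj_p, bGj_m))

      sF <- adam_step(netF, optF, gradF, lr); netF <- sF$net; optF <- sF$opt
      sG <- adam_step(netG, optG, gradG, lr); netG <- sG$net; optG <- sG$opt

      if (it %% 50 == 0 || it == p$iterations) {
        history[[length(history) + 1]] <- c(
          iteration = it, loss = loss,
          ncc = (nF$ncc + nG$ncc) / 2,
          cycle = (cycF + cycG) / 2,
          jacobian = (jF$pen + jG$pen) / 2
        )
      }
    }
    list(netF = netF, netG = netG,
         initial_cycle = initial_cycle, final_cycle = cycle_probe(),
         history = do.call(rbind, history))
  })

  make_eval <- function(net) {
    force(net)
    function(X) {
      X <- matrix(as.numeric(X), ncol = 3)
      scale * siren_forward(net, norm_x(X))$out
    }
  }
  diagnostics <- list(
    backend = "inr",
    iterations = p$iterations,
    history = fit$history,
    final_loss = fit$history[nrow(fit$history), ],
    cycle_residual = fit$final_cycle,
    initial_cycle_residual = fit$initial_cycle,
    seed = p$seed
  )
  new_deformation_model(
    forward = make_eval(fit$netF),
    backward = make_eval(fit$netG),
    roi = roi$indicator,
    diagnostics = diagnostics
  )
}

#' Loss terms of a deformation model on a coordinate batch
#'
#' Reports the three components of the registration objective for an
#' arbitrary bidirectional model: normalized cross-correlation between the
#' intensities of `vol_a` at the batch and `vol_b` at the forward-mapped
#' batch (and symmetrically for the backward map; the mean of the two is
#' returned), the symmetric Jacobian penalty (mean squared log-determinant
#' of the finite-difference Jacobian of either map), and the mean squared
#' cycle residual.
#'
#' @param model A [deformation_model].
#' @param batch n x 3 world coordinates inside the region of interest.
#' @param vol_a,vol_b The two frames.
#' @param fd_step Finite-difference step in mm.
#' @return A list with `ncc`, `jacobian_penalty`, `cycle_penalty`.
#' @export
loss_terms <- function(model, batch, vol_a, vol_b, fd_step = 0.5) {
  batch <- matrix(as.numeric(batch), ncol = 3)
  if (!all(in_fov(vol_a, batch)))
    stop("sampling error: batch contains points outside the image", call. = FALSE)
  dF <- model$forward(batch)
  dG <- model$backward(batch)
  a_fix <- sample_volume(vol_a, batch)
  b_fix <- sample_volume(vol_b, batch)
  nccF <- ncc_with_grad(a_fix, sample_volume(vol_b, batch + dF))$ncc
  nccG <- ncc_with_grad(b_fix, sample_volume(vol_a, batch + dG))$ncc
  jac_pen <- function(fn) {
    m <- nrow(batch)
    Dp <- rbind(fn(batch + matrix(c(fd_step, 0, 0), m, 3, byrow = TRUE)),
                fn(batch + matrix(c(0, fd_step, 0), m, 3, byrow = TRUE)),
                fn(batch + matrix(c(0, 0, fd_step), m, 3, byrow = TRUE)))
    Dm <- rbind(fn(batch - matrix(c(fd_step, 0, 0), m, 3, byrow = TRUE)),
                fn(batch - matrix(c(0, fd_step, 0), m, 3, byrow = TRUE)),
                fn(batch - matrix(c(0, 0, fd_step), m, 3, byrow = TRUE)))
    fd <- fd_jacobian(Dp, Dm, m, fd_step)
    mean(log(pmax(fd$det, 1e-6))^2)
  }
  CF <- model$backward(batch + dF) + dF
  CG <- model$forward(batch + dG) + dG
  list(
    ncc = (nccF + nccG) / 2,
    jacobian_penalty = (jac_pen(model$forward) + jac_pen(model$backward)) / 2,
    cycle_penalty = (sum(CF^2) / nrow(batch) + sum(CG^2) / nrow(batch)) / 2
  )
}

#' Jacobian determinants of a displacement field
#'
#' Finite-difference estimate of `det(I + dD/dx)` for the forward map of a
#' deformation model, at each row of `X`.
#'
#' @param model A [deformation_model] (its forward map is used).
#' @param X n x 3 world coordinates (mm).
#' @param fd_step Finite-difference step in mm.
#' @return Numeric vector of determinants.
#' @export
deformation_jacobian <- function(model, X, fd_step = 0.5) {
  X <- matrix(as.numeric(X), ncol = 3)
  m <- nrow(X)
  fn <- model$forward
  Dp <- rbind(fn(X + matrix(c(fd_step, 0, 0), m, 3, byrow = TRUE)),
              fn(X + matrix(c(0, fd_step, 0), m, 3, byrow = TRUE)),
              fn(X + matrix(c(0, 0, fd_step), m, 3, byrow = TRUE)))
  Dm <- rbind(fn(X - matrix(c(fd_step, 0, 0), m, 3, byrow = TRUE)),
              fn(X - matrix(c(0, fd_step, 0), m, 3, byrow = TRUE)),
              fn(X - matrix(c(0, 0, fd_step), m, 3, byrow = TRUE)))
  fd_jacobian(Dp, Dm, m, fd_step)$det
}

#' Oracle registration backend from a known displacement field
#'
#' Wraps an analytic ground-truth displacement function (e.g. from
#' [generate_phantom()]) as a [deformation_model], so the motility and
#' classification stages can be validated independently of optimisation
#' quality. If no backward function is supplied it is obtained by
#' fixed-point inversion of the forward field.
#'
#' @param forward Function `X -> n x 3` displacement (mm).
#' @param backward Optional exact inverse-direction displacement function.
#' @param roi Optional indicator function; defaults to everywhere-trusted.
#' @param tol Fixed-point inversion tolerance in mm.
#' @param max_iter Maximum fixed-point iterations.
#' @return A [deformation_model].
#' @export
oracle_backend <- function(forward, backward = NULL, roi = NULL,
                           tol = 1e-4, max_iter = 100) {
  fwd <- function(X) forward(matrix(as.numeric(X), ncol = 3))
  bwd <- if (!is.null(backward)) {
    function(X) backward(matrix(as.numeric(X), ncol = 3))
  } else {
    function(X) {
      X <- matrix(as.numeric(X), ncol = 3)
      d <- -fwd(X)
      for (i in seq_len(max_iter)) {
        d_new <- -fwd(X + d)
        if (max(abs(d_new - d)) < tol) return(d_new)
        d <- d_new
      }
      if (max(abs(-fwd(X + d) - d)) > 10 * tol)
        stop("oracle backend: displacement field could not be inverted",
             call. = FALSE)
      d
    }
  }
  new_deformation_model(
    forward = fwd, backward = bwd,
    roi = roi %||% function(X) rep(TRUE, nrow(matrix(as.numeric(X), ncol = 3))),
    diagnostics = list(backend = "oracle")
  )
}

# Oracle model for a phantom frame pair (exact analytic inverse).
phantom_model <- function(phantom, from, to) {
  force(from); force(to)
  new_deformation_model(
    forward = function(X) phantom$truth(X, from, to),
    backward = function(X) phantom$truth(X, to, from),
    roi = function(X) rep(TRUE, nrow(matrix(as.numeric(X), ncol = 3))),
    diagnostics = list(backend = "oracle", from = from, to = to)
  )
}
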