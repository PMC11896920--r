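# Sinusoidal representation network (SIREN) with analytic reverse-mode
# gradients, plus an Adam optimizer and a one-cycle learning-rate schedule.
# Base-R matrix operations only; the networks are small (3 x 256 by default)
# and batches are a few hundred coordinates, so this is fast enough without
# a deep-learning framework.

siren_init <- function(in_dim = 3, out_dim = 3, width = 256,
                       hidden_layers = 3, omega0 = 30, final_scale = 1e-3) {
  W <- list(); b <- list()
  # first layer: U(-1/in, 1/in); hidden: U(+-sqrt(6/fan_in)/omega0)
  W[[1]] <- matrix(runif(in_dim * width, -1 / in_dim, 1 / in_dim), in_dim, width)
  b[[1]] <- numeric(width)
  if (hidden_layers > 1) {
    bound <- sqrt(6 / width) / omega0
    for (l in 2:hidden_layers) {
      W[[l]] <- matrix(runif(width * width, -bound, bound), width, width)
      b[[l]] <- numeric(width)
    }
  }
  bound <- sqrt(6 / width)
  W[[hidden_layers + 1]] <- matrix(
    runif(width * out_dim, -bound, bound) * final_scale, width, out_dim
  )
  b[[hidden_layers + 1]] <- numeric(out_dim)
  list(W = W, b = b, omega0 = omega0, hidden_layers = hidden_layers)
}

# Forward pass; returns the output and the cache needed for backprop.
siren_forward <- function(net, X) {
  L <- net$hidden_layers
  A <- X
  As <- vector("list", L + 1)  # layer inputs
  Zs <- vector("list", L)      # scaled pre-activations
  for (l in seq_len(L)) {
    As[[l]] <- A
    Z <- net$omega0 * (A %*% net$W[[l]] +
                         matrix(net$b[[l]], nrow(A), ncol(net$W[[l]]), byrow = TRUE))
    Zs[[l]] <- Z
    A <- sin(Z)
  }
  As[[L + 1]] <- A
  out <- A %*% net$W[[L + 1]] +
    matrix(net$b[[L + 1]], nrow(A), ncol(net$W[[L + 1]]), byrow = TRUE)
  list(out = out, As = As, Zs = Zs)
}

# Reverse-mode gradients for an upstream dL/d(out); also returns dL/dX
# (needed to chain through network composition in the cycle term).
siren_backward <- function(net, cache, dOut) {
  L <- net$hidden_layers
  gW <- vector("list", L + 1); gb <- vector("list", L + 1)
  gW[[L + 1]] <- crossprod(cache$As[[L + 1]], dOut)
  gb[[L + 1]] <- colSums(dOut)
  dA <- dOut %*% t(net$W[[L + 1]])
  for (l in L:1) {
    dP <- net$omega0 * (dA * cos(cache$Zs[[l]]))
    gW[[l]] <- crossprod(cache$As[[l]], dP)
    gb[[l]] <- colSums(dP)
    dA <- dP %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb, dX = dA)
}

adam_init <- function(net) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  list(
    mW = lapply(net$W, zero_like), vW = lapply(net$W, zero_like),
    mb = lapply(net$b, zero_like), vb = lapply(net$b, zero_like),
    t = 0L
  )
}

adam_step <- function(net, opt, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

# One-cycle policy: linear warm-up from max_lr/25 over `warmup` of the run,
# then cosine annealing down to max_lr/100.
one_cycle_lr <- function(i, total, max_lr, warmup = 0.1) {
  w <- max(1, round(warmup * total))
  if (i <= w) {
    max_lr * (1 / 25 + (1 - 1 / 25) * i / w)
  } else {
    p <- (i - w) / max(1, total - w)
    lo <- max_lr / 100
    lo + (max_lr - lo) * (1 + cos(pi * p)) / 2
  }
}
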