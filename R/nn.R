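# Minimal neural-network engine for the helix WGAN: 1-D convolutions (kernel
# 3, same padding) expressed as matrix products over an unfolded input, ReLU
# ConvBlocks with residual connections, and Adam.
#
# The critic is built exclusively from linear maps and ReLU, so it is
# piecewise linear in its input: its input-gradient depends only on the
# weights and the (locally constant) ReLU masks. That structure is what makes
# the exact gradient-penalty weight-gradient below possible without a general
# higher-order autodiff system: for a fixed co-vector v, v . grad_x D(x) is a
# forward (tangent) pass through the same masked linear network, and its
# weight-gradient is ordinary backprop through that tangent pass.

relu <- function(x) pmax(x, 0)

# Precomputed column indices for unfolding a channel x (L*B) batch into the
# kernel-3 neighborhood stack [left; center; right] with zero padding at the
# per-sample block boundaries.
unfold_idx <- function(L, B) {
  t <- rep(seq_len(L), B)
  j <- seq_len(L * B)
  list(L = L, B = B,
       left = ifelse(t > 1L, j - 1L, 1L),  left_ok = t > 1L,
       right = ifelse(t < L, j + 1L, 1L), right_ok = t < L)
}

nn_unfold <- function(X, ui) {
  XL <- X[, ui$left, drop = FALSE];  XL[, !ui$left_ok] <- 0
  XR <- X[, ui$right, drop = FALSE]; XR[, !ui$right_ok] <- 0
  rbind(XL, X, XR)
}

# Adjoint of nn_unfold: scatter-add the three shifted copies back.
nn_fold <- function(dU, ui, C) {
  dX <- dU[(C + 1L):(2L * C), , drop = FALSE]
  dXL <- dU[seq_len(C), , drop = FALSE]
  dXR <- dU[(2L * C + 1L):(3L * C), , drop = FALSE]
  lo <- ui$left_ok; ro <- ui$right_ok
  dX[, ui$left[lo]] <- dX[, ui$left[lo], drop = FALSE] + dXL[, lo, drop = FALSE]
  dX[, ui$right[ro]] <- dX[, ui$right[ro], drop = FALSE] + dXR[, ro, drop = FALSE]
  dX
}

.flatten <- function(H, CL, B) { dim(H) <- c(CL, B); H }
.unflatten <- function(F_, C, LB) { F_ <- as.matrix(F_); dim(F_) <- c(C, LB); F_ }

.he_init <- function(nout, nin) matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)

# ---- generator -------------------------------------------------------------

gen_init <- function(cfg) {
  C <- cfg$channels; L <- cfg$L; nc <- cfg$n_channels
  par <- list(W0 = .he_init(C * L, cfg$latent_dim), b0 = numeric(C * L))
  for (k in seq_len(cfg$n_blocks)) {
    par[[paste0("Wb", k)]] <- .he_init(C, 3L * C) * 0.5
    par[[paste0("bb", k)]] <- numeric(C)
  }
  par$Wh <- .he_init(nc, C) * 0.5
  par$bh <- numeric(nc)
  par
}

# Forward pass. z: latent x B. Returns Y (n_channels x (L*B)) and, when
# keep = TRUE, the caches backward needs.
gen_forward <- function(par, z, cfg, keep = FALSE) {
  C <- cfg$channels; L <- cfg$L; B <- ncol(z); nc <- cfg$n_channels
  ui <- unfold_idx(L, B)
  A0 <- par$W0 %*% z + par$b0
  H <- .unflatten(relu(A0), C, L * B)
  m0 <- A0 > 0
  blocks <- vector("list", cfg$n_blocks)
  for (k in seq_len(cfg$n_blocks)) {
    U <- nn_unfold(H, ui)
    A <- par[[paste0("Wb", k)]] %*% U + par[[paste0("bb", k)]]
    if (keep) blocks[[k]] <- list(U = U, mask = A > 0)
    H <- H + relu(A)
  }
  Y <- par$Wh %*% H + par$bh
  head_cache <- NULL
  if (cfg$angle_head == "tanh") {
    ar <- (21L):nc
    Y[ar, ] <- tanh(Y[ar, , drop = FALSE])
  } else {
    # radial cap per (sin, cos) pair: y = g / max(||g||, 1). Keeps generated
    # pairs inside the unit disk (real pairs sit on the circle, masked ones at
    # the origin) without the per-channel saturation of tanh, so gradients
    # through the head stay well-conditioned for the latent search.
    np <- (nc - 20L) %/% 2L
    si <- 20L + 2L * seq_len(np) - 1L
    ci <- si + 1L
    nrm <- sqrt(Y[si, , drop = FALSE]^2 + Y[ci, , drop = FALSE]^2)
    sc <- 1 / pmax(nrm, 1)
    head_cache <- list(si = si, ci = ci, nrm = nrm, sc = sc,
                       gs = Y[si, , drop = FALSE], gc = Y[ci, , drop = FALSE])
    Y[si, ] <- Y[si, , drop = FALSE] * sc
    Y[ci, ] <- Y[ci, , drop = FALSE] * sc
  }
  if (!keep) return(Y)
  list(Y = Y, cache = list(z = z, m0 = m0, blocks = blocks, H = H, ui = ui,
                           head = head_cache))
}

# Backward: dY (n_channels x L*B) -> gradients for parameters and/or z.
gen_backward <- function(par, fw, dY, cfg, wrt = c("both", "params", "z")) {
  wrt <- match.arg(wrt)
  C <- cfg$channels; L <- cfg$L
  ca <- fw$cache; ui <- ca$ui; B <- ncol(ca$z)
  if (cfg$angle_head == "tanh") {
    ar <- (21L):cfg$n_channels
    dY[ar, ] <- dY[ar, , drop = FALSE] * (1 - fw$Y[ar, , drop = FALSE]^2)
  } else {
    hc <- ca$head
    over <- hc$nrm > 1
    # inside the disk the head is the identity; outside, y = g/n with
    # dg = (dy - y (y . dy)) / n per pair
    ds <- dY[hc$si, , drop = FALSE]; dc <- dY[hc$ci, , drop = FALSE]
    ys <- hc$gs * hc$sc; yc <- hc$gc * hc$sc
    dot <- ys * ds + yc * dc
    ds2 <- ifelse(over, (ds - ys * dot) / hc$nrm, ds)
    dc2 <- ifelse(over, (dc - yc * dot) / hc$nrm, dc)
    dY[hc$si, ] <- ds2
    dY[hc$ci, ] <- dc2
  }
  grads <- NULL
  if (wrt != "z") grads <- list(Wh = dY %*% t(ca$H), bh = rowSums(dY))
  dH <- t(par$Wh) %*% dY
  for (k in rev(seq_len(cfg$n_blocks))) {
    bl <- ca$blocks[[k]]
    dA <- dH * bl$mask
    if (wrt != "z") {
      grads[[paste0("Wb", k)]] <- dA %*% t(bl$U)
      grads[[paste0("bb", k)]] <- rowSums(dA)
    }
    dH <- dH + nn_fold(t(par[[paste0("Wb", k)]]) %*% dA, ui, C)
  }
  dA0 <- .flatten(dH, C * L, B) * ca$m0
  if (wrt != "z") {
    grads$W0 <- dA0 %*% t(ca$z)
    grads$b0 <- rowSums(dA0)
  }
  dz <- if (wrt != "params") t(par$W0) %*% dA0 else NULL
  list(grads = grads, dz = dz)
}

# ---- critic ----------------------------------------------------------------

critic_init <- function(cfg) {
  C <- cfg$channels; L <- cfg$L; nc <- cfg$n_channels
  nb <- cfg$n_blocks_critic
  if (nb == 0L)
    return(list(wout = .he_init(1L, nc * L), bout = 0))
  par <- list(Wc0 = .he_init(C, 3L * nc), bc0 = numeric(C))
  for (k in seq_len(nb - 1L)) {
    par[[paste0("Wb", k)]] <- .he_init(C, 3L * C) * 0.5
    par[[paste0("bb", k)]] <- numeric(C)
  }
  par$wout <- .he_init(1L, C * L)
  par$bout <- 0
  par
}

# Forward. X: n_channels x (L*B). Returns scores (1 x B) and caches.
critic_forward <- function(par, X, cfg, keep = FALSE) {
  L <- cfg$L; nc <- cfg$n_channels; C <- cfg$channels
  nb <- cfg$n_blocks_critic
  B <- ncol(X) / L
  if (nb == 0L) {
    F_ <- .flatten(X, nc * L, B)
    s <- par$wout %*% F_ + par$bout
    if (!keep) return(s)
    return(list(s = s, cache = list(F = F_, B = B)))
  }
  ui <- unfold_idx(L, B)
  U0 <- nn_unfold(X, ui)
  A0 <- par$Wc0 %*% U0 + par$bc0
  H <- relu(A0)
  m0 <- A0 > 0
  blocks <- vector("list", nb - 1L)
  for (k in seq_len(nb - 1L)) {
    U <- nn_unfold(H, ui)
    A <- par[[paste0("Wb", k)]] %*% U + par[[paste0("bb", k)]]
    if (keep) blocks[[k]] <- list(U = U, mask = A > 0)
    H <- H + relu(A)
  }
  F_ <- .flatten(H, C * L, B)
  s <- par$wout %*% F_ + par$bout
  if (!keep) return(s)
  list(s = s, cache = list(U0 = U0, m0 = m0, blocks = blocks, F = F_, ui = ui, B = B))
}

# Backward for upstream score-gradients ds (1 x B). Returns parameter grads
# and/or the input gradient dX.
critic_backward <- function(par, fw, ds, cfg, wrt = c("both", "params", "input")) {
  wrt <- match.arg(wrt)
  L <- cfg$L; nc <- cfg$n_channels; C <- cfg$channels
  nb <- cfg$n_blocks_critic
  ca <- fw$cache; B <- ca$B
  grads <- NULL
  if (wrt != "input") grads <- list(wout = ds %*% t(ca$F), bout = sum(ds))
  dF <- t(par$wout) %*% ds
  if (nb == 0L) {
    dX <- if (wrt != "params") .unflatten(dF, nc, L * B) else NULL
    return(list(grads = grads, dX = dX))
  }
  ui <- ca$ui
  dH <- .unflatten(dF, C, L * B)
  for (k in rev(seq_len(nb - 1L))) {
    bl <- ca$blocks[[k]]
    dA <- dH * bl$mask
    if (wrt != "input") {
      grads[[paste0("Wb", k)]] <- dA %*% t(bl$U)
      grads[[paste0("bb", k)]] <- rowSums(dA)
    }
    dH <- dH + nn_fold(t(par[[paste0("Wb", k)]]) %*% dA, ui, C)
  }
  dA0 <- dH * ca$m0
  if (wrt != "input") {
    grads$Wc0 <- dA0 %*% t(ca$U0)
    grads$bc0 <- rowSums(dA0)
  }
  dX <- if (wrt != "params") nn_fold(t(par$Wc0) %*% dA0, ui, nc) else NULL
  list(grads = grads, dX = dX)
}

# Exact weight-gradient of sum_b v_b . grad_x D(x_b) for a fixed co-vector
# batch v (n_channels x L*B), with the ReLU masks of the recorded forward
# pass held constant (the a.e.-exact double backward for a piecewise-linear
# critic). Bias gradients are identically zero.
critic_penalty_grads <- function(par, fw, v, cfg) {
  L <- cfg$L; nc <- cfg$n_channels; C <- cfg$channels
  nb <- cfg$n_blocks_critic
  ca <- fw$cache; B <- ca$B
  if (nb == 0L)
    return(list(wout = matrix(rowSums(.flatten(v, nc * L, B)), 1L),
                bout = 0))
  ui <- ca$ui
  # tangent forward
  Ht <- ca$m0 * (par$Wc0 %*% nn_unfold(v, ui))
  tang <- vector("list", nb - 1L)
  for (k in seq_len(nb - 1L)) {
    Ut <- nn_unfold(Ht, ui)
    tang[[k]] <- list(Hin_t = Ht, Ut = Ut)
    Ht <- Ht + ca$blocks[[k]]$mask * (par[[paste0("Wb", k)]] %*% Ut)
  }
  grads <- list(wout = matrix(rowSums(.flatten(Ht, C * L, B)), 1L), bout = 0)
  # backward through the tangent chain
  r <- .unflatten(t(par$wout) %*% matrix(1, 1L, B), C, L * B)
  for (k in rev(seq_len(nb - 1L))) {
    rm_ <- r * ca$blocks[[k]]$mask
    grads[[paste0("Wb", k)]] <- rm_ %*% t(tang[[k]]$Ut)
    grads[[paste0("bb", k)]] <- numeric(C)
    r <- r + nn_fold(t(par[[paste0("Wb", k)]]) %*% rm_, ui, C)
  }
  grads$Wc0 <- (r * ca$m0) %*% t(nn_unfold(v, ui))
  grads$bc0 <- numeric(C)
  grads
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(par) {
  list(t = 0L,
       m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0))
}

adam_step <- function(par, grads, st, lr, beta1 = 0, beta2 = 0.9, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = st)
}

# elementwise sum of two gradient lists
.add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
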