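# The helix WGAN-GP: configuration, model construction, Wasserstein critic
# loss with gradient penalty, training loop and structure sampling.

#' WGAN-GP configuration
#'
#' @param latent_dim latent-space dimension (default 128).
#' @param channels ConvBlock width.
#' @param n_blocks generator ConvBlocks; `n_blocks_critic` critic ConvBlocks
#'   (0 gives a purely linear critic, useful for analytic checks).
#' @param L helix length the model generates (14 by default; 16/18 supported
#'   as separate configs).
#' @param critic_steps critic updates per generator update (default 5).
#' @param lambda_gp gradient-penalty weight (default 10).
#' @param gp_one_sided penalize only gradient norms above one (default TRUE,
#'   matching the "for gradients above one" constraint); FALSE gives the
#'   two-sided textbook penalty.
#' @param lr,beta1,beta2 Adam settings (WGAN-GP practice: beta1 = 0,
#'   beta2 = 0.9).
#' @param batch_size minibatch size.
#' @param seed RNG seed recorded in the model.
#' @param angle_encoding `"sincos"` (42 channels) or `"raw"` (31 channels).
#' @param angle_head generator output activation for the angle channels:
#'   `"pairnorm"` (default; each (sin, cos) pair radially capped to the unit
#'   disk, which matches the unit-circle statistics of encoded real data
#'   without per-channel saturation) or `"tanh"`. The raw encoding always
#'   uses tanh (its channels are not paired).
#' @param probe_size number of fixed latent vectors used to track generation
#'   quality during training (default 500).
#' @return a `gan_config`.
#' @export
gan_config <- function(latent_dim = 128L, channels = 64L, n_blocks = 4L,
                       n_blocks_critic = 4L, L = 14L, critic_steps = 5L,
                       lambda_gp = 10, gp_one_sided = TRUE,
                       lr = 1e-4, beta1 = 0, beta2 = 0.9,
                       batch_size = 64L, seed = 1L,
                       angle_encoding = c("sincos", "raw"),
                       angle_head = c("pairnorm", "tanh"), probe_size = 500L) {
  angle_encoding <- match.arg(angle_encoding)
  angle_head <- match.arg(angle_head)
  if (angle_encoding == "raw") angle_head <- "tanh"
  cfg <- list(latent_dim = as.integer(latent_dim), channels = as.integer(channels),
              n_blocks = as.integer(n_blocks),
              n_blocks_critic = as.integer(n_blocks_critic), L = as.integer(L),
              critic_steps = as.integer(critic_steps), lambda_gp = lambda_gp,
              gp_one_sided = isTRUE(gp_one_sided), lr = lr,
              beta1 = beta1, beta2 = beta2, batch_size = as.integer(batch_size),
              seed = as.integer(seed), angle_encoding = angle_encoding,
              angle_head = angle_head, probe_size = as.integer(probe_size),
              n_channels = if (angle_encoding == "sincos") 42L else 31L)
  stopifnot(cfg$latent_dim > 0, cfg$channels > 0, cfg$L > 0,
            cfg$critic_steps > 0, cfg$lambda_gp >= 0, cfg$batch_size > 0)
  structure(cfg, class = "gan_config")
}

#' Desk-scale configuration
#'
#' A small configuration (latent 64, channels 64, batch 64, Adam lr 1e-3)
#' sized for laptop-scale corpora and the test suite; the full-scale defaults
#' of [gan_config()] remain available for larger corpora.
#'
#' @param ... overrides passed to [gan_config()].
#' @return a `gan_config`.
#' @export
desk_config <- function(...) {
  args <- list(latent_dim = 64L, channels = 64L, batch_size = 64L, lr = 1e-3)
  args[names(list(...))] <- list(...)
  do.call(gan_config, args)
}

#' Initialize a helix GAN model
#'
#' @param config a `gan_config`.
#' @return a `gan_model` with freshly initialized generator and critic.
#' @export
gan_model <- function(config = gan_config()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  structure(list(generator = gen_init(config), critic = critic_init(config),
                 config = config, step = 0L, metrics = NULL),
            class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("<gan_model> L=%d latent=%d channels=%d blocks=%d/%d step=%d\n",
              x$config$L, x$config$latent_dim, x$config$channels,
              x$config$n_blocks, x$config$n_blocks_critic, x$step))
  invisible(x)
}

#' Generate feature maps from latent vectors
#'
#' Deterministic given (model, z) and differentiable with respect to z (the
#' property the constrained latent search relies on).
#'
#' @param model a `gan_model`.
#' @param z latent matrix (latent_dim x B) or a single latent vector.
#' @param as `"fmap"` (list of `helix_fmap`) or `"matrix"` (raw
#'   n_channels x (L*B) output).
#' @return list of feature maps, or the raw output matrix.
#' @export
generate <- function(model, z, as = c("fmap", "matrix")) {
  as <- match.arg(as)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  cfg <- model$config
  if (nrow(z) != cfg$latent_dim)
    stop("latent dimension mismatch: got ", nrow(z), ", expected ", cfg$latent_dim)
  Y <- gen_forward(model$generator, z, cfg)
  if (as == "matrix") return(Y)
  lapply(seq_len(ncol(z)), function(b) {
    m <- t(Y[, (b - 1L) * cfg$L + seq_len(cfg$L), drop = FALSE])
    f <- list(L = cfg$L, seq_block = m[, 1:20, drop = FALSE],
              angle_block = m[, -(1:20), drop = FALSE], mask = NULL,
              angle_encoding = cfg$angle_encoding)
    class(f) <- "helix_fmap"
    f
  })
}

# Stack a list of feature maps into the critic's n_channels x (L*B) layout.
fmaps_to_batch <- function(fmaps) {
  do.call(cbind, lapply(fmaps, function(f) t(fmap_matrix(f))))
}

#' Wasserstein critic loss with gradient penalty
#'
#' The critic objective `E[D(fake)] - E[D(real)]` plus
#' `lambda * E[max(0, ||grad_x D(xhat)|| - 1)^2]` on uniform real/fake
#' interpolates (the two-sided variant squares `||grad|| - 1` directly).
#' With `lambda = 0` this reduces to the plain Wasserstein objective.
#'
#' @param model a `gan_model`.
#' @param real,fake batches: lists of `helix_fmap` or n_channels x (L*B)
#'   matrices of equal shape.
#' @param lambda penalty weight; defaults to the model configuration.
#' @param eps optional per-sample interpolation weights in \[0, 1\] (random
#'   when NULL).
#' @return list with `wasserstein`, `penalty`, `total` and the per-sample
#'   interpolate gradient norms `grad_norms`.
#' @export
critic_loss <- function(model, real, fake, lambda = NULL, eps = NULL) {
  cfg <- model$config
  if (is.list(real)) real <- fmaps_to_batch(real)
  if (is.list(fake)) fake <- fmaps_to_batch(fake)
  stopifnot(all(dim(real) == dim(fake)))
  if (is.null(lambda)) lambda <- cfg$lambda_gp
  B <- ncol(real) / cfg$L
  s_real <- critic_forward(model$critic, real, cfg)
  s_fake <- critic_forward(model$critic, fake, cfg)
  w <- mean(s_fake) - mean(s_real)
  gp <- .gp_terms(model$critic, real, fake, cfg, lambda, eps = eps)
  list(wasserstein = w, penalty = gp$value, total = w + gp$value,
       grad_norms = gp$norms)
}

# Gradient-penalty value, per-sample norms, interpolates and the co-vector v
# feeding the double backward.
.gp_terms <- function(par_d, real, fake, cfg, lambda, eps = NULL) {
  B <- ncol(real) / cfg$L
  if (is.null(eps)) eps <- stats::runif(B)
  ecol <- rep(eps, each = cfg$L)
  xhat <- sweep(real, 2, ecol, `*`) + sweep(fake, 2, 1 - ecol, `*`)
  fw <- critic_forward(par_d, xhat, cfg, keep = TRUE)
  g <- critic_backward(par_d, fw, matrix(1, 1L, B), cfg, wrt = "input")$dX
  gsq <- colSums(.flatten(g^2, cfg$n_channels * cfg$L, B))
  u <- sqrt(pmax(gsq, 1e-12))
  excess <- if (cfg$gp_one_sided) pmax(u - 1, 0) else (u - 1)
  value <- lambda * mean(excess^2)
  coef <- (2 * lambda / B) * excess / u
  v <- sweep(g, 2, rep(coef, each = cfg$L), `*`)
  list(value = value, norms = u, xhat = xhat, fw = fw, v = v)
}

#' Train the WGAN-GP on an encoded corpus
#'
#' Alternating optimization with `critic_steps` critic updates per generator
#' update. The metrics log records, per epoch, the critic's Wasserstein
#' estimate and the surrogate-quality pass fraction on a fixed probe of
#' latent vectors drawn once before training (epoch 0 is the untrained
#' model). A non-finite loss aborts training and returns the last finite
#' epoch checkpoint with status `"aborted_nan"`.
#'
#' @param model a `gan_model`.
#' @param corpus a `helix_corpus` at the model's L (all records are used;
#'   restrict to a split beforehand if desired).
#' @param epochs number of passes over the corpus.
#' @param verbose print per-epoch progress.
#' @return the trained `gan_model`; `$metrics` holds the per-epoch log,
#'   `$probe_z` the fixed probe latents.
#' @export
train_gan <- function(model, corpus, epochs = 30L, verbose = FALSE) {
  cfg <- model$config
  if (corpus$L != cfg$L) stop("corpus L != model L")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed + model$step)

  X_all <- do.call(cbind, lapply(corpus$records, function(r)
    t(fmap_matrix(encode(r$seq, r$ics, angle_encoding = cfg$angle_encoding)))))
  n <- length(corpus)
  B <- min(cfg$batch_size, n)

  if (is.null(model$probe_z))
    model$probe_z <- matrix(stats::rnorm(cfg$latent_dim * cfg$probe_size),
                            cfg$latent_dim)
  st_d <- adam_init(model$critic)
  st_g <- adam_init(model$generator)

  metrics <- data.frame(epoch = 0L, wasserstein = NA_real_,
                        probe_pass = surrogate_pass_fraction(model, model$probe_z))
  if (verbose) message(sprintf("epoch %3d  probe_pass %.3f", 0L, metrics$probe_pass[1]))
  snapshot <- model
  col_of <- function(idx) {
    cols <- rep((idx - 1L) * cfg$L, each = cfg$L) + seq_len(cfg$L)
    X_all[, cols, drop = FALSE]
  }

  kstep <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    w_est <- c()
    for (start in seq(1L, n - B + 1L, by = B)) {
      idx <- ord[start:(start + B - 1L)]
      real <- col_of(idx)
      # critic update
      z <- matrix(stats::rnorm(cfg$latent_dim * B), cfg$latent_dim)
      fake <- gen_forward(model$generator, z, cfg)
      fw_r <- critic_forward(model$critic, real, cfg, keep = TRUE)
      fw_f <- critic_forward(model$critic, fake, cfg, keep = TRUE)
      g_r <- critic_backward(model$critic, fw_r, matrix(-1 / B, 1L, B), cfg,
                             wrt = "params")$grads
      g_f <- critic_backward(model$critic, fw_f, matrix(1 / B, 1L, B), cfg,
                             wrt = "params")$grads
      gp <- .gp_terms(model$critic, real, fake, cfg, cfg$lambda_gp)
      g_p <- critic_penalty_grads(model$critic, gp$fw, gp$v, cfg)
      grads <- .add_grads(.add_grads(g_r, g_f), g_p)
      upd <- adam_step(model$critic, grads, st_d, cfg$lr, cfg$beta1, cfg$beta2)
      model$critic <- upd$par; st_d <- upd$state
      w_est <- c(w_est, mean(fw_f$s) - mean(fw_r$s))
      kstep <- kstep + 1L
      # generator update every critic_steps critic updates
      if (kstep %% cfg$critic_steps == 0L) {
        z <- matrix(stats::rnorm(cfg$latent_dim * B), cfg$latent_dim)
        fwg <- gen_forward(model$generator, z, cfg, keep = TRUE)
        fwd <- critic_forward(model$critic, fwg$Y, cfg, keep = TRUE)
        dX <- critic_backward(model$critic, fwd, matrix(-1 / B, 1L, B), cfg,
                              wrt = "input")$dX
        gg <- gen_backward(model$generator, fwg, dX, cfg, wrt = "params")$grads
        upd <- adam_step(model$generator, gg, st_g, cfg$lr, cfg$beta1, cfg$beta2)
        model$generator <- upd$par; st_g <- upd$state
        model$step <- model$step + 1L
      }
    }
    finite <- all(is.finite(w_est)) &&
      all(vapply(model$generator, function(p) all(is.finite(p)), TRUE)) &&
      all(vapply(model$critic, function(p) all(is.finite(p)), TRUE))
    if (!finite) {
      warning("non-finite loss at epoch ", ep,
              "; aborting with the last finite checkpoint")
      snapshot$status <- "aborted_nan"
      snapshot$metrics <- metrics
      return(snapshot)
    }
    pp <- surrogate_pass_fraction(model, model$probe_z)
    metrics <- rbind(metrics,
                     data.frame(epoch = ep, wasserstein = mean(w_est), probe_pass = pp))
    if (verbose)
      message(sprintf("epoch %3d  W %.4f  probe_pass %.3f", ep, mean(w_est), pp))
    snapshot <- model
    snapshot$metrics <- metrics
  }
  model$metrics <- metrics
  model$status <- "trained"
  model
}

#' Fraction of probe latents decoding to surrogate-passing helices
#'
#' @param model a `gan_model`.
#' @param z latent matrix (defaults to the model's stored probe).
#' @return fraction in \[0, 1\].
#' @export
surrogate_pass_fraction <- function(model, z = model$probe_z) {
  fmaps <- generate(model, z)
  mean(vapply(fmaps, function(f) {
    d <- decode(f)
    h <- reconstruct(d$seq, d$ics)
    surrogate_quality(h)$pass
  }, TRUE))
}

#' Sample full-atom helices from the model
#'
#' Standard-normal latents, decode, reconstruct; for D chirality the mirror
#' transformation is applied to the reconstructed L-helix.
#'
#' @param model a `gan_model`.
#' @param n number of structures (0 gives an empty list).
#' @param seed RNG seed.
#' @param chirality `"L"` or `"D"`.
#' @return list of `atomic_helix`.
#' @export
sample_structures <- function(model, n, seed = 1L, chirality = c("L", "D")) {
  chirality <- match.arg(chirality)
  if (n == 0L) return(list())
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  z <- matrix(stats::rnorm(model$config$latent_dim * n), model$config$latent_dim)
  fmaps <- generate(model, z)
  lapply(fmaps, function(f) {
    d <- decode(f)
    h <- reconstruct(d$seq, d$ics)
    if (chirality == "D") h <- mirror_transform(h) else h
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds the configuration as JSON (human-readable,
#' recorded verbatim) and the parameter blobs plus training state.
#'
#' @param model a `gan_model`.
#' @param path checkpoint directory.
#' @return invisibly `path` / the restored `gan_model`.
#' @export
save_gan <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model[setdiff(names(model), "config")], file.path(path, "params.rds"))
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  cfg <- jsonlite::read_json(file.path(path, "config.json"), simplifyVector = TRUE)
  cfg <- do.call(gan_config, cfg[setdiff(names(cfg), "n_channels")])
  rest <- readRDS(file.path(path, "params.rds"))
  model <- c(rest, list(config = cfg))
  class(model) <- "gan_model"
  model
}
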