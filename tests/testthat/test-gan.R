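# WGAN-GP mechanics: gradients, penalty analytics, determinism,
# checkpointing, sampling.

test_that("generator and critic gradients match finite differences", {
  set.seed(31)
  cfg <- gan_config(latent_dim = 6L, channels = 5L, n_blocks = 2L,
                    n_blocks_critic = 2L, L = 5L)
  pg <- helixforge:::gen_init(cfg)
  pd <- helixforge:::critic_init(cfg)
  # keep pre-activations away from the ReLU kink
  for (nm in names(pg)) if (startsWith(nm, "b")) pg[[nm]] <- rnorm(length(pg[[nm]]), 0, 0.3)
  for (nm in names(pd)) if (startsWith(nm, "b") && nm != "bout")
    pd[[nm]] <- rnorm(length(pd[[nm]]), 0, 0.3)
  B <- 2L; hh <- 1e-6
  z <- matrix(rnorm(cfg$latent_dim * B), cfg$latent_dim)
  Wr <- matrix(rnorm(cfg$n_channels * cfg$L * B), cfg$n_channels)
  fw <- helixforge:::gen_forward(pg, z, cfg, keep = TRUE)
  bk <- helixforge:::gen_backward(pg, fw, Wr, cfg, wrt = "both")
  lossY <- function(p, zz) sum(Wr * helixforge:::gen_forward(p, zz, cfg))
  for (nm in names(pg)) {
    i <- sample(length(pg[[nm]]), 1)
    pp <- pg; pp[[nm]][i] <- pp[[nm]][i] + hh; f1 <- lossY(pp, z)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * hh; f0 <- lossY(pp, z)
    expect_equal(bk$grads[[nm]][i], (f1 - f0) / (2 * hh), tolerance = 1e-4)
  }
  i <- sample(length(z), 1)
  zp <- z; zp[i] <- zp[i] + hh; f1 <- lossY(pg, zp)
  zp[i] <- zp[i] - 2 * hh; f0 <- lossY(pg, zp)
  expect_equal(bk$dz[i], (f1 - f0) / (2 * hh), tolerance = 1e-4)

  X <- matrix(rnorm(cfg$n_channels * cfg$L * B), cfg$n_channels)
  ds <- matrix(runif(B), 1)
  fwd <- helixforge:::critic_forward(pd, X, cfg, keep = TRUE)
  bkd <- helixforge:::critic_backward(pd, fwd, ds, cfg, wrt = "both")
  sfun <- function(p, XX) sum(ds * helixforge:::critic_forward(p, XX, cfg))
  for (nm in names(pd)) {
    i <- sample(length(pd[[nm]]), 1)
    pp <- pd; pp[[nm]][i] <- pp[[nm]][i] + hh; f1 <- sfun(pp, X)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * hh; f0 <- sfun(pp, X)
    expect_equal(bkd$grads[[nm]][i], (f1 - f0) / (2 * hh), tolerance = 1e-4)
  }
  i <- sample(length(X), 1)
  Xp <- X; Xp[i] <- Xp[i] + hh; f1 <- sfun(pd, Xp)
  Xp[i] <- Xp[i] - 2 * hh; f0 <- sfun(pd, Xp)
  expect_equal(bkd$dX[i], (f1 - f0) / (2 * hh), tolerance = 1e-4)
})

test_that("gradient-penalty weight gradients match finite differences", {
  set.seed(33)
  cfg <- gan_config(latent_dim = 6L, channels = 5L, n_blocks = 2L,
                    n_blocks_critic = 3L, L = 5L)
  pd <- helixforge:::critic_init(cfg)
  for (nm in names(pd)) if (startsWith(nm, "b") && nm != "bout")
    pd[[nm]] <- rnorm(length(pd[[nm]]), 0, 0.3)
  B <- 3L; lam <- 10; hh <- 1e-6
  real <- matrix(rnorm(cfg$n_channels * cfg$L * B), cfg$n_channels)
  fake <- matrix(rnorm(cfg$n_channels * cfg$L * B), cfg$n_channels)
  eps <- runif(B)
  gp <- helixforge:::.gp_terms(pd, real, fake, cfg, lam, eps = eps)
  g <- helixforge:::critic_penalty_grads(pd, gp$fw, gp$v, cfg)
  penval <- function(p) helixforge:::.gp_terms(p, real, fake, cfg, lam, eps = eps)$value
  for (nm in c("Wc0", "Wb1", "Wb2", "wout")) {
    for (r in 1:3) {
      i <- sample(length(pd[[nm]]), 1)
      pp <- pd; pp[[nm]][i] <- pp[[nm]][i] + hh; f1 <- penval(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * hh; f0 <- penval(pp)
      expect_equal(g[[nm]][i], (f1 - f0) / (2 * hh), tolerance = 1e-3)
    }
  }
})

test_that("a 1-Lipschitz linear critic incurs exactly zero penalty", {
  cfg <- gan_config(latent_dim = 6L, channels = 4L, n_blocks = 1L,
                    n_blocks_critic = 0L, L = 5L, seed = 3L)
  model <- gan_model(cfg)
  model$critic$wout <- model$critic$wout / sqrt(sum(model$critic$wout^2))
  set.seed(12)
  B <- 4L
  real <- matrix(rnorm(cfg$n_channels * cfg$L * B), cfg$n_channels)
  fake <- matrix(rnorm(cfg$n_channels * cfg$L * B), cfg$n_channels)
  cl <- critic_loss(model, real, fake)
  expect_equal(cl$penalty, 0)
  expect_true(all(abs(cl$grad_norms - 1) < 1e-12))
  # scaling the critic above the Lipschitz bound grows the penalty
  # monotonically, following lambda * (c - 1)^2 exactly for a linear critic
  pens <- vapply(c(1.5, 2, 3), function(cc) {
    m2 <- model; m2$critic$wout <- model$critic$wout * cc
    critic_loss(m2, real, fake)$penalty
  }, 0)
  expect_equal(pens, 10 * (c(1.5, 2, 3) - 1)^2, tolerance = 1e-9)
  expect_true(all(diff(pens) > 0))
})

test_that("lambda = 0 reduces the critic loss to the plain Wasserstein objective", {
  model <- tiny_model()
  set.seed(13)
  cfg <- model$config
  real <- matrix(rnorm(cfg$n_channels * cfg$L * 4), cfg$n_channels)
  fake <- matrix(rnorm(cfg$n_channels * cfg$L * 4), cfg$n_channels)
  cl <- critic_loss(model, real, fake, lambda = 0)
  expect_equal(cl$total, cl$wasserstein)
  expect_equal(cl$penalty, 0)
  # identical batches under a zero critic: Wasserstein term is exactly 0
  m0 <- model
  for (nm in names(m0$critic)) m0$critic[[nm]] <- m0$critic[[nm]] * 0
  expect_equal(critic_loss(m0, real, real, lambda = 0)$wasserstein, 0)
})

test_that("generation is deterministic, shape-checked and always decodable", {
  model <- tiny_model()
  set.seed(17)
  z <- matrix(rnorm(model$config$latent_dim * 3), model$config$latent_dim)
  a <- generate(model, z, as = "matrix")
  b <- generate(model, z, as = "matrix")
  expect_identical(a, b)
  fmaps <- generate(model, z)
  expect_length(fmaps, 3L)
  for (f in fmaps) {
    d <- decode(f)
    expect_true(all(d$seq %in% AA_ALPHABET))
    expect_s3_class(reconstruct(d$seq, d$ics), "atomic_helix")
  }
  expect_error(generate(model, rnorm(7)), "dimension mismatch")
})

test_that("an untrained generator rarely passes the surrogate gate", {
  model <- tiny_model()
  set.seed(19)
  z <- matrix(rnorm(model$config$latent_dim * 60), model$config$latent_dim)
  expect_lt(surrogate_pass_fraction(model, z), 0.5)
})

test_that("seed-fixed training is bitwise reproducible and logs fixed-probe metrics", {
  cfg <- gan_config(latent_dim = 8L, channels = 8L, n_blocks = 1L,
                    n_blocks_critic = 1L, L = 14L, batch_size = 16L,
                    seed = 23L, probe_size = 5L)
  co <- make_synthetic_corpus(32, seed = 14)
  m1 <- train_gan(gan_model(cfg), co, epochs = 2L)
  m2 <- train_gan(gan_model(cfg), co, epochs = 2L)
  expect_identical(m1$generator, m2$generator)
  expect_identical(m1$critic, m2$critic)
  expect_identical(m1$probe_z, m2$probe_z)
  expect_equal(nrow(m1$metrics), 3L)  # epoch 0 + 2
  expect_identical(m1$metrics, m2$metrics)
  # the input corpus is never mutated
  expect_identical(co, make_synthetic_corpus(32, seed = 14))
})

test_that("checkpoints round-trip the model exactly", {
  model <- tiny_model()
  path <- tempfile()
  save_gan(model, path)
  back <- load_gan(path)
  set.seed(29)
  z <- matrix(rnorm(model$config$latent_dim * 2), model$config$latent_dim)
  expect_identical(generate(model, z, as = "matrix"),
                   generate(back, z, as = "matrix"))
  expect_equal(back$config$lambda_gp, model$config$lambda_gp)
  unlink(path, recursive = TRUE)
})

test_that("sampling respects seed, count and chirality", {
  model <- tiny_model()
  expect_identical(sample_structures(model, 0L), list())
  a <- sample_structures(model, 3L, seed = 7)
  b <- sample_structures(model, 3L, seed = 7)
  expect_equal(helix_coords(a[[1]]), helix_coords(b[[1]]))
  d <- sample_structures(model, 3L, seed = 7, chirality = "D")
  for (i in 1:3) {
    expect_identical(d[[i]]$chirality, "D")
    # same latents: the D sample is exactly the mirror of the L sample
    expect_equal(helix_coords(d[[i]]),
                 helix_coords(mirror_transform(a[[i]])), tolerance = 1e-12)
    ch <- validate_helix(d[[i]], strict = FALSE)
    expect_length(ch$bad_chirality, 0L)
  }
})
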