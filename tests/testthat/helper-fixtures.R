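# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

# A tiny differentiable model (untrained): enough for search/geometry
# plumbing, cheap enough for every test file.
tiny_model <- function() {
  if (is.null(.fx$tiny))
    .fx$tiny <- gan_model(gan_config(latent_dim = 16L, channels = 16L,
                                     n_blocks = 2L, n_blocks_critic = 2L,
                                     L = 14L, batch_size = 16L, seed = 5L,
                                     probe_size = 10L))
  .fx$tiny
}

small_corpus <- function() {
  if (is.null(.fx$corpus)) .fx$corpus <- make_synthetic_corpus(80, seed = 21)
  .fx$corpus
}

# Independent RMSD oracle: brute-force random-quaternion search plus local
# polish, never touching the Kabsch path.
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rmsd_oracle <- function(mobile, reference, n_grid = 1500L, n_polish = 4L) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) sqrt(mean(rowSums((A %*% t(quat_rotation(q)) - B)^2)))
  qs <- matrix(stats::rnorm(4L * n_grid), ncol = 4L)
  vals <- apply(qs, 1, obj)
  best <- order(vals)[seq_len(n_polish)]
  mins <- vapply(best, function(i)
    stats::optim(qs[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))$value, 0)
  min(c(vals, mins))
}

# A plant-and-recover hotspot case: target taken from the model's own output
# at a known latent, so a perfect solution exists by construction.
plant_case <- function(model, seed, positions = c(3L, 6L, 10L)) {
  set.seed(seed)
  z_star <- matrix(stats::rnorm(model$config$latent_dim), ncol = 1)
  d <- decode(generate(model, z_star)[[1]])
  h <- reconstruct(d$seq, d$ics)
  list(z_star = z_star, helix = h, spec = hotspot_spec_from_helix(h, positions))
}
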