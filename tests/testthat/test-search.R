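# Constrained latent-space search: assignment enumeration, loss behavior,
# ranking and recovery.

test_that("assignment enumeration preserves spacings at every feasible offset", {
  h <- ideal_helix("ADKLEADKLEADKL")
  mk <- function(pos) hotspot_spec_from_helix(h, pos)
  expect_length(enumerate_assignments(mk(c(1, 3, 6)), 14L), 9L)  # spacings 2,3
  expect_length(enumerate_assignments(mk(5), 14L), 14L)          # single hotspot
  expect_length(enumerate_assignments(mk(c(1, 8)), 14L), 7L)
  # spacings 7,7 need index 15: infeasible
  spec77 <- mk(c(1, 8))
  spec77$spacings <- c(7L, 7L)
  spec77$types <- c(spec77$types, spec77$types[1])
  spec77$coords <- c(spec77$coords, spec77$coords[1])
  spec77$resno <- c(spec77$resno, 15L)
  expect_length(enumerate_assignments(spec77, 14L), 0L)
  # every enumerated assignment reproduces the spacings exactly
  for (a in enumerate_assignments(mk(c(2, 5, 11)), 14L))
    expect_identical(diff(a), mk(c(2, 5, 11))$spacings)
})

test_that("assignment counts match brute-force enumeration for all patterns", {
  L <- 14L
  brute <- function(spacings) {
    pos <- utils::combn(L, length(spacings) + 1L, simplify = FALSE)
    sum(vapply(pos, function(p) identical(diff(p), as.integer(spacings)), TRUE))
  }
  set.seed(10)
  for (k in 1:3) {
    for (rep in 1:8) {
      spacings <- sample(1:6, k, replace = TRUE)
      h <- ideal_helix(strrep("A", 14))
      spec <- hotspot_spec_from_helix(h, cumsum(c(1, spacings)) [cumsum(c(1, spacings)) <= 14])
      if (length(spec$types) != k + 1) next
      n <- length(enumerate_assignments(spec, L))
      expect_identical(n, max(0L, L - sum(spacings)))
      expect_identical(n, brute(spacings))
    }
  }
})

test_that("the search loss is minimal at a planted optimum and non-negative", {
  model <- tiny_model()
  pc <- plant_case(model, seed = 51)
  pos <- c(3L, 6L, 10L)
  # angle term vanishes at the planted latent (pair directions match exactly);
  # hinged CE contributes nothing once the argmax holds with confidence, so
  # the total is bounded by the cross-entropy floor
  l_star <- search_loss(model, pc$z_star, pc$spec, pos)
  l_plain <- search_loss(model, pc$z_star, pc$spec, pos, ce_mode = "plain")
  expect_gte(l_plain, l_star)
  set.seed(52)
  for (i in 1:5) {
    z <- matrix(rnorm(model$config$latent_dim), ncol = 1)
    expect_gte(search_loss(model, z, pc$spec, pos), 0)
  }
})

test_that("optimization decreases the loss on a recoverable target", {
  model <- tiny_model()
  pc <- plant_case(model, seed = 53)
  res <- latent_search(model, pc$spec, n_restarts = 2L, steps = 50L, seed = 3,
                       assignments = list(c(3L, 6L, 10L)))
  for (r in res) {
    tr <- r$loss_trace
    expect_lt(tr[length(tr)], tr[1])
  }
})

test_that("results are ranked by RMSD with unmatched candidates last", {
  model <- tiny_model()
  pc <- plant_case(model, seed = 54)
  res <- latent_search(model, pc$spec, n_restarts = 4L, steps = 40L, seed = 9)
  matched <- vapply(res, `[[`, TRUE, "matched")
  rmsds <- vapply(res, `[[`, 0, "rmsd")
  if (any(matched) && any(!matched))
    expect_lt(max(which(matched)), min(which(!matched)))
  expect_true(all(diff(rmsds[matched]) >= -1e-12))
  for (r in res) {
    expect_identical(r$rmsd >= 0 || !r$matched, TRUE)
    expect_identical(diff(r$assignment), pc$spec$spacings)
  }
})

test_that("infeasible hotspot spans return an empty result with a status", {
  model <- tiny_model()
  h <- ideal_helix(strrep("A", 14))
  spec <- hotspot_spec_from_helix(h, c(1L, 8L))
  spec$spacings <- 14L
  out <- latent_search(model, spec, n_restarts = 1L, steps = 1L)
  expect_length(out, 0L)
  expect_match(attr(out, "status"), "no feasible")
})

test_that("the angle surrogate ranks candidates consistently with backbone RMSD", {
  model <- tiny_model()
  pc <- plant_case(model, seed = 57)
  pos <- c(3L, 6L, 10L)
  set.seed(58)
  Z <- matrix(rnorm(model$config$latent_dim * 100), model$config$latent_dim)
  fmaps <- generate(model, Z)
  tgt <- do.call(rbind, lapply(pos, function(i)
    helixforge:::residue_coords(pc$helix, i)[c("N", "CA", "C", "O"), ]))
  surrogate <- numeric(100); true_rmsd <- numeric(100)
  for (b in 1:100) {
    # angle-term only (drop the sequence part by using the planted types)
    Yb <- t(fmap_matrix(fmaps[[b]]))
    hl <- helixforge:::.hotspot_loss_block(Yb, pc$spec, pos, 1.0)
    d <- decode(fmaps[[b]])
    h <- reconstruct(d$seq, d$ics)
    mob <- do.call(rbind, lapply(pos, function(i)
      helixforge:::residue_coords(h, i)[c("N", "CA", "C", "O"), ]))
    surrogate[b] <- hl$loss
    true_rmsd[b] <- superpose(mob, tgt)$rmsd
  }
  expect_gt(cor(surrogate, true_rmsd, method = "spearman"), 0)
})

test_that("batch evaluation summarizes bins whose fractions sum to one", {
  model <- tiny_model()
  expect_identical(nrow(batch_evaluate(model, list())), 0L)
  co <- identity_split(small_corpus(), seed = 2)
  cases <- make_hotspot_cases(co, seed = 3)[1:2]
  out <- batch_evaluate(model, cases, chirality = "L",
                        budget = list(n_restarts = 2L, steps = 30L), seed = 4)
  expect_equal(nrow(out), 2L)
  fr <- attr(out, "fractions")
  expect_equal(sum(fr), 1)
  expect_true(all(levels(out$bin) == c("matched", "intermediate", "poor")))
  # D bins split at 2.0 instead of 2.5
  expect_identical(as.character(rmsd_bin(c(1.4, 2.2, 2.7), "L")),
                   c("matched", "intermediate", "poor"))
  expect_identical(as.character(rmsd_bin(c(1.4, 1.8, 2.2), "D")),
                   c("matched", "intermediate", "poor"))
})

test_that("seed-fixed searches are fully reproducible", {
  model <- tiny_model()
  pc <- plant_case(model, seed = 59)
  a <- latent_search(model, pc$spec, n_restarts = 2L, steps = 25L, seed = 6)
  b <- latent_search(model, pc$spec, n_restarts = 2L, steps = 25L, seed = 6)
  expect_equal(vapply(a, `[[`, 0, "rmsd"), vapply(b, `[[`, 0, "rmsd"))
  expect_equal(a[[1]]$z, b[[1]]$z)
})
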