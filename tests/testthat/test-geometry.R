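# Internal-coordinate reconstruction, measurement, mirror transform and
# superposition.

deg <- function(x) x * pi / 180

random_record <- function(seed, L = 14L) {
  set.seed(seed)
  seq <- sample(setdiff(AA_ALPHABET, "P"), L, replace = TRUE)
  chi_mask <- helixforge:::default_chi_mask(seq)
  chi <- matrix(0, L, 5)
  chi[chi_mask] <- runif(sum(chi_mask), -pi, pi)
  list(seq = seq,
       ics = helix_ics(phi = deg(-57) + rnorm(L, 0, 0.15),
                       psi = deg(-47) + rnorm(L, 0, 0.15),
                       omega = pi + rnorm(L, 0, 0.05),
                       tau_n = rep(deg(121.7), L) + rnorm(L, 0, 0.02),
                       tau_ca = rep(deg(111.2), L) + rnorm(L, 0, 0.02),
                       tau_c = rep(deg(116.2), L) + rnorm(L, 0, 0.02),
                       chi = chi, chi_mask = chi_mask))
}

max_angle_err <- function(a, b) {
  err <- 0
  for (nm in c("phi", "psi", "omega", "tau_n", "tau_ca", "tau_c")) {
    msk <- a$bb_mask[, nm] & b$bb_mask[, nm]
    err <- max(err, max(abs(wrap_angle(a[[nm]][msk] - b[[nm]][msk]))))
  }
  msk <- a$chi_mask & b$chi_mask
  max(err, max(abs(wrap_angle(a$chi[msk] - b$chi[msk]))))
}

test_that("measure_internal inverts reconstruct on random records", {
  for (seed in 1:8) {
    rec <- random_record(seed)
    h <- reconstruct(rec$seq, rec$ics)
    m <- measure_internal(h)
    expect_identical(m$seq, rec$seq)
    expect_equal(m$ics$chi_mask, rec$ics$chi_mask)
    expect_lt(max_angle_err(m$ics, rec$ics), 1e-6)
    # Cartesian round trip
    h2 <- reconstruct(m$seq, m$ics)
    expect_lt(superpose(helix_coords(h2), helix_coords(h))$rmsd, 1e-3)
  }
})

test_that("ideal helix has canonical rise, turn and hydrogen-bond geometry", {
  h <- ideal_helix(strrep("A", 14))
  CA <- helixforge:::atom_by_residue(h, "CA")
  X <- sweep(CA, 2, colMeans(CA))
  ax <- svd(X)$v[, 1]
  rise <- abs(mean(diff(CA %*% ax)))
  expect_gt(rise, 1.4); expect_lt(rise, 1.6)
  proj <- X - (X %*% ax) %*% t(ax)
  ang <- vapply(1:13, function(i) {
    u <- proj[i, ]; v <- proj[i + 1, ]
    atan2(sum(helixforge:::.cross(u, v) * ax), sum(u * v))
  }, 0)
  expect_equal(2 * pi / abs(mean(ang)), 3.6, tolerance = 0.03)
  O <- helixforge:::atom_by_residue(h, "O")
  N <- helixforge:::atom_by_residue(h, "N")
  dON <- sqrt(rowSums((O[1:10, ] - N[5:14, ])^2))
  expect_true(all(dON > 2.7 & dON < 3.3))
})

test_that("topology table gives glycine no CB and rejects bad chi masks", {
  g <- ideal_helix("G")
  expect_identical(sort(g$atoms$elety), sort(c("N", "CA", "C", "O")))
  expect_equal(length(g), 1L)
  # a chi slot alanine does not have
  ics <- ideal_helix_ics(2, seq = c("A", "A"))
  ics$chi_mask[1, 1] <- TRUE
  expect_error(reconstruct(c("A", "A"), ics), "lacks")
  expect_error(reconstruct("A", ideal_helix_ics(2, seq = "AA")), "lengths differ")
  expect_error(aa_three("X"), "unknown residue")
})

test_that("mirror transform is an involution, an isometry, and negates dihedrals", {
  rec <- random_record(42)
  h <- reconstruct(rec$seq, rec$ics)
  hm <- mirror_transform(h)
  expect_identical(hm$chirality, "D")
  # involution
  back <- mirror_transform(hm)
  expect_identical(back$chirality, "L")
  expect_lt(max(abs(helix_coords(back) - helix_coords(h))), 1e-9)
  # isometry: all pairwise distances preserved
  expect_equal(as.vector(dist(helix_coords(hm))),
               as.vector(dist(helix_coords(h))), tolerance = 1e-12)
  # dihedral negation, bond angles unchanged
  m <- measure_internal(h); mm <- measure_internal(hm)
  for (nm in c("phi", "psi", "omega")) {
    msk <- m$ics$bb_mask[, nm]
    expect_lt(max(abs(wrap_angle(mm$ics[[nm]][msk] + m$ics[[nm]][msk]))), 1e-9)
  }
  for (nm in c("tau_n", "tau_ca", "tau_c"))
    expect_equal(mm$ics[[nm]], m$ics[[nm]], tolerance = 1e-12)
  expect_lt(max(abs(wrap_angle(mm$ics$chi[m$ics$chi_mask] + m$ics$chi[m$ics$chi_mask]))), 1e-9)
  # mirrored helix occupies the alpha_L region
  ok <- mm$ics$bb_mask[, "phi"] & mm$ics$bb_mask[, "psi"]
  expect_true(all(ramachandran_class(mm$ics$phi[ok], mm$ics$psi[ok]) == "alpha_L"))
})

test_that("superposition recovers rigid motions and never reflects", {
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(30), ncol = 3)
    th <- runif(3, -pi, pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2])), 3, 3)
    Y <- X %*% t(Rz %*% Rx) + matrix(rnorm(3), nrow(X), 3, byrow = TRUE)
    sp <- superpose(X, Y)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_superposition(sp, X), Y, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # chiral cloud vs its mirror image: proper rotations cannot undo reflection
  X <- matrix(rnorm(15), ncol = 3)
  Xm <- X; Xm[, 3] <- -Xm[, 3]
  expect_gt(superpose(Xm, X)$rmsd, 0.1)
  # degenerate input flagged, not silent
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_true(superpose(line, line)$degenerate)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(superpose(X[1:4, ], X), "atom counts differ")
})

test_that("superposition rmsd is invariant to pre-rotation of either input", {
  set.seed(8)
  X <- matrix(rnorm(21), ncol = 3)
  Y <- X + matrix(rnorm(21, 0, 0.3), ncol = 3)
  base <- superpose(X, Y)$rmsd
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(superpose(X %*% t(R), Y)$rmsd, base, tolerance = 1e-9)
  expect_equal(superpose(X, Y %*% t(R))$rmsd, base, tolerance = 1e-9)
})

test_that("partial RMSD is zero for verbatim hotspots and enforces identity", {
  rec <- random_record(11)
  h <- reconstruct(rec$seq, rec$ics)
  spec <- hotspot_spec_from_helix(h, c(2L, 5L, 9L))
  expect_equal(as.numeric(partial_rmsd(h, spec, c(2L, 5L, 9L))), 0, tolerance = 1e-9)
  # definition: equals plain superposition on the flattened atom union
  mob <- do.call(rbind, lapply(c(2L, 5L, 9L), function(i)
    helixforge:::residue_coords(h, i)))
  ref <- do.call(rbind, spec$coords)   # same residues, same atom order
  expect_equal(as.numeric(partial_rmsd(h, spec, c(2L, 5L, 9L))),
               superpose(mob, ref)$rmsd, tolerance = 1e-12)
  # identity requirement
  other <- which(rec$seq != rec$seq[2])[1]
  expect_error(partial_rmsd(h, spec, c(other, 5L, 9L)), "mismatch")
})

test_that("Ramachandran boxes classify canonical conformations", {
  expect_identical(ramachandran_class(deg(-57), deg(-47)), "alpha_R")
  expect_identical(ramachandran_class(deg(57), deg(47)), "alpha_L")
  expect_identical(ramachandran_class(deg(-120), deg(130)), "beta")
  expect_identical(ramachandran_class(deg(10), deg(-170)), "other")
  # mirror symmetry of the helical boxes
  set.seed(3)
  p <- runif(200, -pi, pi); s <- runif(200, -pi, pi)
  a <- ramachandran_class(p, s); b <- ramachandran_class(-p, -s)
  expect_identical(a == "alpha_R", b == "alpha_L")
})

test_that("degenerate dihedrals measure as masked values, never NaN", {
  h <- ideal_helix("AAA")
  # flatten a psi-defining quadruple: put N(2) on the N1-CA1-C1 line
  a <- h$atoms
  ca1 <- unlist(a[a$residue_index == 1 & a$elety == "CA", c("x", "y", "z")])
  c1 <- unlist(a[a$residue_index == 1 & a$elety == "C", c("x", "y", "z")])
  dir <- (c1 - ca1) / sqrt(sum((c1 - ca1)^2))
  a[a$residue_index == 2 & a$elety == "N", c("x", "y", "z")] <-
    as.list(c1 + dir * 1.33)
  h2 <- atomic_helix(a, chirality = "L")
  m <- measure_internal(h2, check_continuity = FALSE)
  expect_false(any(is.na(unlist(m$ics[c("phi", "psi", "omega")]))))
  expect_false(m$ics$bb_mask[1, "psi"])
})

test_that("PDB round trip preserves coordinates, numbering and chirality", {
  h <- mirror_transform(ideal_helix("ADKLE", resno_start = 7L))
  f <- tempfile(fileext = ".pdb")
  write_helix_pdb(h, f)
  h2 <- read_helix_pdb(f)
  expect_identical(h2$chirality, "D")
  expect_identical(helix_seq(h2), helix_seq(h))
  expect_equal(unique(h2$atoms$resno), 7:11)
  expect_equal(helix_coords(h2), helix_coords(h), tolerance = 1e-3,
               ignore_attr = TRUE)
  unlink(f)
})
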