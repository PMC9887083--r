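# Fragment planning, mutation, joining and the analog pipeline plumbing.

test_that("the GLP-1 plan reproduces its ranges, hotspots and overlaps", {
  plan <- glp1_plan()
  expect_equal(plan$ranges, list(c(7L, 20L), c(12L, 25L), c(23L, 36L)))
  expect_equal(plan$hotspots, list(c(7L, 9L, 12L), c(13L, 15L, 19L), c(28L, 29L, 32L)))
  ov <- plan_overlaps(plan)
  expect_equal(ov[[1]], c(12L, 20L))        # 9 shared residues
  expect_equal(ov[[1]][2] - ov[[1]][1] + 1L, 9L)
  # the shipped plan file parses to the same plan
  f <- system.file("extdata", "glp1_plan.yaml", package = "helixforge")
  expect_equal(read_plan(f)$ranges, plan$ranges)
  expect_equal(read_plan(f)$hotspots, plan$hotspots)
  # and the synthetic target carries the right residues at the hotspots
  g <- synthetic_glp1_helix()
  sq <- helix_seq(g)
  resno <- unique(g$atoms$resno)
  expect_identical(sq[match(c(7, 9, 12, 13, 15, 19, 28, 29, 32), resno)],
                   c("H", "E", "F", "T", "D", "Y", "F", "I", "L"))
})

test_that("automatic fragment planning covers the target with overlaps", {
  g <- synthetic_glp1_helix()
  plan <- plan_fragments(g, fragment_length = 14L, hotspots = c(9L, 25L, 33L))
  expect_gte(length(plan$ranges), 2L)
  for (f in seq_along(plan$ranges)[-1]) {
    ov <- plan$ranges[[f - 1]][2] - plan$ranges[[f]][1] + 1L
    expect_gte(ov, 2L)
  }
  expect_equal(plan$ranges[[1]][1], 7L)
  expect_equal(plan$ranges[[length(plan$ranges)]][2], 36L)
  # 14-residue target: a single fragment, no joins
  h14 <- ideal_helix(strrep("A", 14))
  p1 <- plan_fragments(h14, 14L)
  expect_length(p1$ranges, 1L)
  expect_error(plan_fragments(g, 14L, hotspots = 99L), "outside")
})

test_that("point mutation rebuilds only the side chain", {
  h <- ideal_helix("AYKLA")
  phe <- mutate_residue(h, 2L, "F")
  expect_identical(helix_seq(phe)[2], "F")
  nm_y <- rownames(helixforge:::residue_coords(h, 2))
  nm_f <- rownames(helixforge:::residue_coords(phe, 2))
  expect_identical(setdiff(nm_y, nm_f), "OH")   # TYR -> PHE drops the hydroxyl
  # chi1/chi2 preserved
  my <- measure_internal(h); mf <- measure_internal(phe)
  expect_equal(mf$ics$chi[2, 1:2], my$ics$chi[2, 1:2], tolerance = 1e-9)
  # backbone untouched
  bb <- c("N", "CA", "C", "O")
  expect_equal(helixforge:::residue_coords(phe, 2)[bb, ],
               helixforge:::residue_coords(h, 2)[bb, ], tolerance = 1e-12)
  # ALA -> GLY removes CB, zero backbone RMSD
  gly <- mutate_residue(h, 1L, "G")
  expect_false("CB" %in% rownames(helixforge:::residue_coords(gly, 1)))
  expect_equal(helixforge:::residue_coords(gly, 1)[bb, ],
               helixforge:::residue_coords(h, 1)[bb, ], tolerance = 1e-12)
  # TYR -> PHE -> TYR restores the original heavy-atom set and coordinates
  back <- mutate_residue(phe, 2L, "Y")
  expect_identical(sort(rownames(helixforge:::residue_coords(back, 2))), sort(nm_y))
  expect_equal(helixforge:::residue_coords(back, 2)[nm_y, ],
               helixforge:::residue_coords(h, 2)[nm_y, ], tolerance = 1e-6)
  # a D-helix mutates through the mirror correctly
  hd <- mirror_transform(h)
  phd <- mutate_residue(hd, 2L, "F")
  expect_identical(phd$chirality, "D")
  expect_length(validate_helix(phd, strict = FALSE)$bad_chirality, 0L)
})

test_that("self-join of identical fragments reproduces the helix", {
  h <- ideal_helix(strrep("ADKLE", 4))   # 20-mer, resno 1..20
  plan <- fragment_plan(ranges = list(c(1L, 14L), c(7L, 20L)),
                        hotspots = list(integer(0), integer(0)))
  f1 <- subset_helix(h, 1:14)
  f2 <- subset_helix(h, 7:20)
  joined <- join_fragments(list(f1, f2), plan)
  expect_equal(length(joined), 20L)
  expect_lt(superpose(helix_coords(joined), helix_coords(h))$rmsd, 1e-6)
  expect_true(validate_helix(joined, strict = FALSE)$ok)
})

test_that("three ideal GLP-1 fragments join into one continuous 30-mer", {
  g <- synthetic_glp1_helix()
  plan <- glp1_plan()
  frags <- lapply(plan$ranges, function(r) {
    resno <- g$atoms$resno[!duplicated(g$atoms$residue_index)]
    subset_helix(g, which(resno >= r[1] & resno <= r[2]))
  })
  joined <- join_fragments(frags, plan)
  expect_equal(length(joined), 30L)
  N <- helixforge:::atom_by_residue(joined, "N")
  C <- helixforge:::atom_by_residue(joined, "C")
  d <- sqrt(rowSums((N[-1, ] - C[-30, ])^2))
  expect_true(all(d >= 1.2 & d <= 1.5))
  expect_true(validate_helix(joined, strict = FALSE)$ok)
  # a mirrored fragment is chirally incompatible: refused with the RMSD
  frags_bad <- frags
  frags_bad[[2]] <- mirror_transform(frags_bad[[2]])
  expect_error(join_fragments(frags_bad, plan), "mixed chirality")
  frags_bad[[2]]$chirality <- "L"   # lie about the flag: geometry still clashes
  expect_error(join_fragments(frags_bad, plan), "incompatible")
})

test_that("plan files round-trip through YAML", {
  plan <- fragment_plan(ranges = list(c(1L, 14L), c(10L, 23L)),
                        hotspots = list(c(2L, 5L), c(12L, 20L)),
                        mutations = list(list(fragment = 2L, position = 12L,
                                              new_type = "F")))
  f <- tempfile(fileext = ".yaml")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$ranges, plan$ranges)
  expect_equal(back$hotspots, plan$hotspots)
  expect_equal(back$mutations[[1]]$new_type, "F")
  unlink(f)
})

test_that("fragment plans validate ordering and overlap", {
  expect_error(fragment_plan(list(c(1L, 14L), c(14L, 27L)),
                             list(integer(0), integer(0))), "overlap")
  expect_error(fragment_plan(list(c(10L, 23L), c(1L, 14L)),
                             list(integer(0), integer(0))), "ordered")
  expect_error(fragment_plan(list(c(1L, 14L)), list(20L)), "outside")
})

test_that("single-fragment analog design reduces to plant-and-recover", {
  model <- tiny_model()
  case <- plant_case(model, seed = 61, positions = c(3L, 7L, 11L))
  target <- case$helix
  plan <- plan_fragments(target, 14L,
                         hotspots = sort(unique(target$atoms$resno))[c(3, 7, 11)])
  des <- design_analog(target, plan, model, chirality = "L",
                       budget = list(n_restarts = 4L, steps = 120L), seed = 2)
  expect_s3_class(des$analog, "atomic_helix")
  expect_equal(nrow(des$report), 1L)
  expect_true(is.finite(des$hotspot_rmsd))
  expect_equal(des$report$rmsd[1], des$fragment_results[[1]]$rmsd)
  # D-mode produces a D analog with negated dihedrals
  desd <- design_analog(target, plan, model, chirality = "D",
                        budget = list(n_restarts = 4L, steps = 120L), seed = 2)
  expect_identical(desd$analog$chirality, "D")
  # CB improper dihedrals consistent with D chirality throughout
  chk <- validate_helix(desd$analog, strict = FALSE)
  expect_length(chk$bad_chirality, 0L)
  expect_length(chk$bad_bonds, 0L)
  # the D analog's dihedrals are the negation of its own mirror's
  md <- measure_internal(desd$analog, check_continuity = FALSE)
  mm <- measure_internal(mirror_transform(desd$analog), check_continuity = FALSE)
  msk <- md$ics$bb_mask[, "phi"]
  expect_lt(max(abs(wrap_angle(md$ics$phi[msk] + mm$ics$phi[msk]))), 1e-9)
})
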