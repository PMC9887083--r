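# Corpus construction: helix extraction from PDB structures, a synthetic
# idealized-helix generator, the sequence-identity train/test split, and
# hotspot test-case generation.

#' Helix corpus
#'
#' @param records list of records, each `list(seq, ics, provenance, split)`.
#' @param L window length shared by all records.
#' @return an object of class `helix_corpus`.
#' @export
helix_corpus <- function(records, L) {
  stopifnot(all(vapply(records, function(r) length(r$seq), 0L) == L))
  structure(list(records = records, L = L), class = "helix_corpus")
}

#' @export
length.helix_corpus <- function(x) length(x$records)

#' @export
print.helix_corpus <- function(x, ...) {
  sp <- corpus_manifest(x)$split
  cat(sprintf("<helix_corpus> %d records of length %d (%d train / %d test / %d unsplit)\n",
              length(x), x$L, sum(sp == "train"), sum(sp == "test"), sum(is.na(sp))))
  invisible(x)
}

#' Record manifest of a corpus
#'
#' @param corpus a `helix_corpus`.
#' @return data.frame with `seq`, `provenance`, `split` per record.
#' @export
corpus_manifest <- function(corpus) {
  data.frame(
    seq = vapply(corpus$records, function(r) paste(r$seq, collapse = ""), ""),
    provenance = vapply(corpus$records, function(r) r$provenance %||% "unknown", ""),
    split = vapply(corpus$records, function(r) r$split %||% NA_character_, ""),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract fixed-length helix windows from a structure
#'
#' Finds maximal runs of residues whose defined (phi, psi) lie in the alpha_R
#' Ramachandran box with unbroken chain continuity, and emits every length-L
#' sliding window (stride 1) over each run as one record. Windows with missing
#' backbone atoms are skipped; duplicate windows (identical sequence and
#' angles to 1e-3 rad) are deduplicated.
#'
#' @param structure an `atomic_helix`, or a PDB file path (all protein chains
#'   are scanned).
#' @param L window length.
#' @param tag provenance tag prefix (defaults to the file name or "helix").
#' @return list of records (`seq`, `ics`, `provenance`).
#' @export
extract_helices <- function(structure, L = 14L, tag = NULL) {
  if (is.character(structure)) {
    pdb <- bio3d::read.pdb(structure)
    chains <- unique(pdb$atom$chain[pdb$atom$type == "ATOM"])
    tag <- tag %||% sub("\\.pdb$", "", basename(structure))
    out <- list()
    for (ch in chains) {
      h <- tryCatch(read_helix_pdb(structure, chain = ch), error = function(e) NULL)
      if (!is.null(h))
        out <- c(out, extract_helices(h, L = L, tag = paste0(tag, "_", ch)))
    }
    return(.dedup_records(out))
  }
  h <- structure
  tag <- tag %||% "helix"
  n <- length(h)
  if (n < L) return(list())

  # residue-level usability: full backbone present
  N <- atom_by_residue(h, "N"); CA <- atom_by_residue(h, "CA")
  C <- atom_by_residue(h, "C"); O <- atom_by_residue(h, "O")
  usable <- !apply(is.na(N) | is.na(CA) | is.na(C) | is.na(O), 1, any)
  # chain continuity between consecutive residues
  cont <- c(FALSE, sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2))
            >= 1.2 &
              sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2)) <= 1.5)
  # dihedrals of usable stretches
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  ii <- which(usable)
  if (length(ii)) {
    prev_ok <- ii[ii > 1 & usable[pmax(ii - 1, 1)] & cont[ii]]
    if (length(prev_ok))
      phi[prev_ok] <- dihedral_angle_many(C[prev_ok - 1L, , drop = FALSE],
                                          N[prev_ok, , drop = FALSE],
                                          CA[prev_ok, , drop = FALSE],
                                          C[prev_ok, , drop = FALSE])
    nxt_ok <- ii[ii < n & usable[pmin(ii + 1, n)] & cont[pmin(ii + 1, n)]]
    if (length(nxt_ok))
      psi[nxt_ok] <- dihedral_angle_many(N[nxt_ok, , drop = FALSE],
                                         CA[nxt_ok, , drop = FALSE],
                                         C[nxt_ok, , drop = FALSE],
                                         N[nxt_ok + 1L, , drop = FALSE])
    psi[ii[ii == n]] <- NA  # terminal psi handled leniently below
  }
  # a residue is helical if every defined angle of (phi, psi) is alpha_R
  in_box <- function(p, s) {
    pd <- p * 180 / pi; sd <- s * 180 / pi
    (is.na(p) | (pd > -100 & pd < -30)) & (is.na(s) | (sd > -80 & sd < -5))
  }
  helical <- usable & in_box(phi, psi)
  # a run starts where helicity begins or the chain breaks
  start <- helical & (c(TRUE, !helical[-n]) | !cont)
  run_id <- cumsum(start)
  runs <- split(which(helical), run_id[helical])

  out <- list()
  for (r in runs) {
    if (length(r) < L) next
    # contiguity within the run (guard against index gaps)
    if (any(diff(r) != 1L)) next
    for (s in seq_len(length(r) - L + 1L)) {
      idx <- r[s:(s + L - 1L)]
      sub <- subset_helix(h, idx)
      rec <- tryCatch({
        m <- measure_internal(sub)
        list(seq = m$seq, ics = m$ics,
             provenance = sprintf("%s:%d-%d", tag, h$atoms$resno[match(idx[1], h$atoms$residue_index)],
                                  h$atoms$resno[match(idx[L], h$atoms$residue_index)]))
      }, error = function(e) NULL)
      if (!is.null(rec)) out <- c(out, list(rec))
    }
  }
  .dedup_records(out)
}

.dedup_records <- function(records) {
  if (length(records) < 2) return(records)
  key <- vapply(records, function(r) {
    am <- .angles_matrix(r$ics)
    paste(c(r$seq, sprintf("%.3f", am$vals * am$mask)), collapse = "|")
  }, "")
  records[!duplicated(key)]
}

#' Extract a sub-helix by residue indices
#'
#' @param h an `atomic_helix`.
#' @param idx increasing residue indices (need not start at 1).
#' @return an `atomic_helix` with residues renumbered 1..length(idx) in
#'   `residue_index` (author `resno` preserved).
#' @export
subset_helix <- function(h, idx) {
  a <- h$atoms[h$atoms$residue_index %in% idx, , drop = FALSE]
  a$residue_index <- match(a$residue_index, sort(unique(a$residue_index)))
  atomic_helix(a, chirality = h$chirality, chain_id = h$chain_id)
}

#' Generate a synthetic idealized-helix corpus
#'
#' Sequences are drawn from a helix-propensity-weighted residue distribution
#' (alanine/leucine/glutamate/lysine enriched; proline excluded from interior
#' positions); backbone torsions are the ideal helix values (-57, -47, 180
#' degrees) plus independent Gaussian noise; main-chain bond angles are fixed
#' at their ideal values; chi slots are drawn from the canonical rotamer means
#' (gauche-, trans, gauche+) with 10 degrees of noise. Fully reproducible from
#' the seed.
#'
#' @param n number of records.
#' @param seed RNG seed.
#' @param noise_sd backbone torsion noise, degrees (default 7).
#' @param L record length (default 14).
#' @return a `helix_corpus` (records unsplit).
#' @export
make_synthetic_corpus <- function(n, seed = 1L, noise_sd = 7, L = 14L) {
  stopifnot(n >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  w_int <- .HELIX_PROPENSITY / sum(.HELIX_PROPENSITY)
  w_first <- .HELIX_PROPENSITY; w_first["P"] <- 0.01
  w_first <- w_first / sum(w_first)
  sd_r <- .deg(noise_sd)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    seq <- c(sample(AA_ALPHABET, 1, prob = w_first),
             sample(AA_ALPHABET, L - 1L, replace = TRUE, prob = w_int))
    nchi <- chi_count(seq)
    chi <- matrix(0, L, 5)
    chi_mask <- default_chi_mask(seq)
    nslots <- sum(chi_mask)
    if (nslots > 0) {
      means <- sample(.ROTAMER_MEANS, nslots, replace = TRUE, prob = .ROTAMER_WEIGHTS)
      chi[chi_mask] <- .deg(means + stats::rnorm(nslots, 0, 10))
    }
    ics <- helix_ics(
      phi = .deg(-57) + stats::rnorm(L, 0, sd_r),
      psi = .deg(-47) + stats::rnorm(L, 0, sd_r),
      omega = pi + stats::rnorm(L, 0, sd_r),
      tau_n = rep(.IDEAL$tau_n, L), tau_ca = rep(.IDEAL$tau_ca, L),
      tau_c = rep(.IDEAL$tau_c, L),
      chi = chi, chi_mask = chi_mask)
    records[[i]] <- list(seq = seq, ics = ics, provenance = "synthetic")
  }
  helix_corpus(records, L)
}

.save_rng <- function() if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", old, .GlobalEnv)
}

#' Assign an identity-filtered train/test split
#'
#' Randomly nominates a candidate test set, then moves every candidate whose
#' sequence identity to any train record exceeds the threshold back into the
#' train set, so the final test set satisfies the <= threshold invariant by
#' construction.
#'
#' @param corpus a `helix_corpus`.
#' @param threshold_percent identity threshold in percent, in (0, 100]
#'   (default 42.8, the 6-of-14 boundary).
#' @param seed RNG seed.
#' @param test_fraction fraction nominated for the test set (default 0.2).
#' @return the corpus with `split` assigned on every record.
#' @export
identity_split <- function(corpus, threshold_percent = 42.8, seed = 1L,
                           test_fraction = 0.2) {
  stopifnot(threshold_percent > 0, threshold_percent <= 100)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- length(corpus)
  seqs <- lapply(corpus$records, `[[`, "seq")
  cand <- sample(n, max(1L, round(n * test_fraction)))
  train <- setdiff(seq_len(n), cand)
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    idv <- vapply(train, function(i) sequence_identity(seqs[[cand[j]]], seqs[[i]]), 0)
    # exact duplicates of a train record are never test material, even at
    # a 100% threshold
    keep[j] <- all(idv <= threshold_percent & idv < 100)
  }
  test <- cand[keep]
  train <- sort(c(train, cand[!keep]))
  if (length(test) == 0)
    warning("identity filter removed every test candidate; test set is empty")
  for (i in train) corpus$records[[i]]$split <- "train"
  for (i in test) corpus$records[[i]]$split <- "test"
  corpus
}

#' Hotspot specification
#'
#' The design constraint: ordered hotspot residues with identity, reference
#' heavy-atom coordinates and register spacings.
#'
#' @param types one-letter residue codes of the hotspots.
#' @param coords list of coordinate matrices (rownames = atom names), one per
#'   hotspot, including at least N, CA, C.
#' @param resno source residue numbers.
#' @param spacings successive index gaps in the source helix
#'   (length `length(types) - 1`).
#' @param ics_rows optional k x 22 matrix of the hotspots' encoded angle
#'   channels plus attribute mask (used by the differentiable search loss).
#' @return an object of class `hotspot_spec`.
#' @export
hotspot_spec <- function(types, coords, resno, spacings, ics_rows = NULL) {
  k <- length(types)
  stopifnot(k >= 1, length(coords) == k, length(resno) == k,
            length(spacings) == k - 1L, all(spacings > 0))
  for (j in seq_len(k))
    if (!all(c("N", "CA", "C") %in% rownames(coords[[j]])))
      stop("hotspot ", j, " reference must include backbone N, CA, C")
  structure(list(types = aa_one(types), coords = coords, resno = resno,
                 spacings = as.integer(spacings), ics_rows = ics_rows),
            class = "hotspot_spec")
}

#' @export
print.hotspot_spec <- function(x, ...) {
  cat(sprintf("<hotspot_spec> %s at resno %s (spacings %s)\n",
              paste(x$types, collapse = ","), paste(x$resno, collapse = ","),
              paste(x$spacings, collapse = ",")))
  invisible(x)
}

#' Build a hotspot specification from residues of a helix
#'
#' @param h an `atomic_helix`.
#' @param positions residue indices of the hotspots (ascending).
#' @return a `hotspot_spec` carrying the residues' heavy-atom coordinates and
#'   encoded angle rows.
#' @export
hotspot_spec_from_helix <- function(h, positions) {
  positions <- sort(as.integer(positions))
  m <- measure_internal(h, check_continuity = FALSE)
  enc <- encode(m$seq, m$ics)
  hotspot_spec(types = m$seq[positions],
               coords = lapply(positions, function(i) residue_coords(h, i)),
               resno = h$atoms$resno[match(positions, h$atoms$residue_index)],
               spacings = diff(positions),
               ics_rows = structure(enc$angle_block[positions, , drop = FALSE],
                                    mask = enc$mask[positions, , drop = FALSE]))
}

#' Mirror a hotspot specification
#'
#' Reflects the reference coordinates through the xy-plane and negates the
#' encoded dihedral angles (their sin channels flip, cos channels are even);
#' bond angles are invariant under reflection. Searching an L-helix against
#' the mirrored specification is, by isometry, equivalent to searching a
#' D-helix against the original.
#'
#' @param spec a `hotspot_spec`.
#' @return the mirrored `hotspot_spec`.
#' @export
mirror_spec <- function(spec) {
  spec$coords <- lapply(spec$coords, function(m) { m[, 3] <- -m[, 3]; m })
  if (!is.null(spec$ics_rows)) {
    msk <- attr(spec$ics_rows, "mask")
    dihedral <- which(!(ANGLE_NAMES %in% c("tau_n", "tau_ca", "tau_c")))
    sin_cols <- 2L * dihedral - 1L
    spec$ics_rows[, sin_cols] <- -spec$ics_rows[, sin_cols, drop = FALSE]
    attr(spec$ics_rows, "mask") <- msk
  }
  spec
}

#' Build hotspot test cases from the test split of a corpus
#'
#' For each test record (or a random fraction of them), draws k distinct
#' positions uniformly without replacement, reconstructs the record and builds
#' the hotspot specification from those residues.
#'
#' @param corpus a split `helix_corpus`.
#' @param k_hotspots number of hotspots per case (default 3).
#' @param seed RNG seed.
#' @param fraction fraction of test records to turn into cases (default 1).
#' @return list of `hotspot_test_case`: `list(record_index, positions, spec)`.
#' @export
make_hotspot_cases <- function(corpus, k_hotspots = 3L, seed = 1L, fraction = 1) {
  if (k_hotspots > corpus$L) stop("k_hotspots exceeds record length")
  test_idx <- which(vapply(corpus$records, function(r) identical(r$split, "test"), TRUE))
  if (length(test_idx) == 0) stop("corpus has no test split")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (fraction < 1)
    test_idx <- sort(sample(test_idx, round(length(test_idx) * fraction)))
  lapply(test_idx, function(i) {
    rec <- corpus$records[[i]]
    pos <- sort(sample.int(corpus$L, k_hotspots))
    h <- reconstruct(rec$seq, rec$ics)
    structure(list(record_index = i, positions = pos,
                   spec = hotspot_spec_from_helix(h, pos)),
              class = "hotspot_test_case")
  })
}
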