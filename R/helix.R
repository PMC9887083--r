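# Containers: per-residue internal coordinates (struct-of-arrays) and the
# full-atom helix, plus PDB input/output through bio3d.

#' Per-residue internal coordinates of a helix
#'
#' A struct-of-arrays container holding, for each of the L residues, the
#' backbone torsions phi/psi/omega, the main-chain bond angles tau_n
#' (C(i-1)-N-CA), tau_ca (N-CA-C) and tau_c (CA-C-N(i+1)), and five side-chain
#' chi slots with a validity mask. All angles are radians in (-pi, pi]; masked
#' entries carry 0. By convention the last residue's psi is defined through its
#' carbonyl O (psi = dihedral(N,CA,C,O) - pi), so it is never masked; phi(1),
#' omega(L), tau_n(1) and tau_c(L) are masked.
#'
#' @param phi,psi,omega,tau_n,tau_ca,tau_c numeric vectors of length L (radians).
#' @param chi L x 5 matrix of side-chain dihedrals (radians).
#' @param bb_mask L x 6 logical matrix (columns phi, psi, omega, tau_n, tau_ca,
#'   tau_c): TRUE where the angle is defined.
#' @param chi_mask L x 5 logical matrix: TRUE where the chi slot is active.
#' @return an object of class `helix_ics`.
#' @export
helix_ics <- function(phi, psi, omega, tau_n, tau_ca, tau_c, chi,
                      bb_mask = NULL, chi_mask = NULL) {
  L <- length(phi)
  stopifnot(length(psi) == L, length(omega) == L, length(tau_n) == L,
            length(tau_ca) == L, length(tau_c) == L,
            is.matrix(chi), nrow(chi) == L, ncol(chi) == 5L)
  if (is.null(bb_mask)) {
    bb_mask <- matrix(TRUE, L, 6, dimnames = list(NULL, .BB_ANGLE_NAMES))
    bb_mask[1L, c("phi", "tau_n")] <- FALSE
    bb_mask[L, c("omega", "tau_c")] <- FALSE
  }
  if (is.null(chi_mask)) chi_mask <- matrix(TRUE, L, 5)
  colnames(bb_mask) <- .BB_ANGLE_NAMES
  ics <- list(phi = wrap_angle(phi), psi = wrap_angle(psi), omega = wrap_angle(omega),
              tau_n = wrap_angle(tau_n), tau_ca = wrap_angle(tau_ca),
              tau_c = wrap_angle(tau_c),
              chi = wrap_angle(chi) * chi_mask,   # masked slots carry 0
              bb_mask = bb_mask, chi_mask = chi_mask)
  for (nm in .BB_ANGLE_NAMES) ics[[nm]][!bb_mask[, nm]] <- 0
  dim(ics$chi) <- c(L, 5L)
  structure(ics, class = "helix_ics")
}

.BB_ANGLE_NAMES <- c("phi", "psi", "omega", "tau_n", "tau_ca", "tau_c")

#' @export
length.helix_ics <- function(x) length(x$phi)

#' @export
print.helix_ics <- function(x, ...) {
  cat(sprintf("<helix_ics> %d residues; mean phi/psi = %.1f/%.1f deg\n",
              length(x),
              mean(x$phi[x$bb_mask[, "phi"]]) * 180 / pi,
              mean(x$psi[x$bb_mask[, "psi"]]) * 180 / pi))
  invisible(x)
}

# Default chi masks for a sequence: slot k active iff k <= chi_count(aa).
default_chi_mask <- function(seq) {
  k <- chi_count(seq)
  t(vapply(k, function(n) seq_len(5) <= n, logical(5)))
}

#' Full-atom helix structure
#'
#' @param atoms data.frame with columns `residue_index`, `resno`, `resname`
#'   (three-letter), `elety` (atom name) and `x`, `y`, `z` in Angstrom.
#' @param chirality `"L"` or `"D"`.
#' @param chain_id single-character chain identifier.
#' @return an object of class `atomic_helix`.
#' @export
atomic_helix <- function(atoms, chirality = c("L", "D"), chain_id = "A") {
  chirality <- match.arg(chirality)
  stopifnot(all(c("residue_index", "resno", "resname", "elety", "x", "y", "z")
                %in% names(atoms)))
  structure(list(atoms = atoms, chirality = chirality, chain_id = chain_id),
            class = "atomic_helix")
}

#' @export
length.atomic_helix <- function(x) length(unique(x$atoms$residue_index))

#' One-letter sequence of a helix
#' @param h an `atomic_helix`.
#' @return character vector of one-letter codes.
#' @export
helix_seq <- function(h) {
  a <- h$atoms
  aa_one(a$resname[!duplicated(a$residue_index)])
}

#' @export
print.atomic_helix <- function(x, ...) {
  cat(sprintf("<atomic_helix> %d residues (%s), chirality %s, chain %s, %d atoms\n",
              length(x), paste(helix_seq(x), collapse = ""),
              x$chirality, x$chain_id, nrow(x$atoms)))
  invisible(x)
}

# n x 3 coordinate matrix (rownames = atom names) of one residue.
residue_coords <- function(h, i) {
  a <- h$atoms[h$atoms$residue_index == i, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$elety
  m
}

#' All atom coordinates of a helix
#' @param h an `atomic_helix`.
#' @return n x 3 numeric matrix in Angstrom, in atom storage order.
#' @export
helix_coords <- function(h) as.matrix(h$atoms[, c("x", "y", "z")])

`helix_coords<-` <- function(h, value) {
  h$atoms[, c("x", "y", "z")] <- value
  h
}

# Coordinates of one named atom per residue (L x 3), NA rows if absent.
atom_by_residue <- function(h, name) {
  a <- h$atoms
  L <- length(h)
  out <- matrix(NA_real_, L, 3)
  sel <- a$elety == name
  out[a$residue_index[sel], ] <- as.matrix(a[sel, c("x", "y", "z")])
  out
}

#' Validate the chain-continuity and chirality invariants of a helix
#'
#' Checks that every residue has the four backbone atoms, that consecutive
#' C(i)-N(i+1) distances lie in the 1.2-1.5 Angstrom peptide-bond range, and
#' that the sign of the CA improper dihedral N-CA-C-CB is consistent with the
#' declared chirality (negative for L).
#'
#' @param h an `atomic_helix`.
#' @param strict error (TRUE) or return a diagnostic list (FALSE).
#' @return invisibly TRUE, or a list with fields `ok`, `bad_backbone`,
#'   `bad_bonds`, `bad_chirality` when `strict = FALSE`.
#' @export
validate_helix <- function(h, strict = TRUE) {
  L <- length(h)
  N <- atom_by_residue(h, "N"); CA <- atom_by_residue(h, "CA")
  C <- atom_by_residue(h, "C"); O <- atom_by_residue(h, "O")
  bad_bb <- which(apply(is.na(N) | is.na(CA) | is.na(C) | is.na(O), 1, any))
  d <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-L, , drop = FALSE])^2))
  bad_bond <- which(d < 1.2 | d > 1.5)
  CB <- atom_by_residue(h, "CB")
  has_cb <- !is.na(CB[, 1])
  bad_chir <- integer(0)
  if (any(has_cb) && length(bad_bb) == 0) {
    idx <- which(has_cb)
    imp <- dihedral_angle_many(N[idx, , drop = FALSE], CA[idx, , drop = FALSE],
                               C[idx, , drop = FALSE], CB[idx, , drop = FALSE])
    want_neg <- h$chirality == "L"
    bad_chir <- idx[if (want_neg) imp > 0 else imp < 0]
  }
  ok <- length(bad_bb) == 0 && length(bad_bond) == 0 && length(bad_chir) == 0
  if (strict && !ok)
    stop(sprintf("invalid helix: missing backbone at [%s]; bad C-N bonds after [%s]; chirality mismatch at [%s]",
                 paste(bad_bb, collapse = ","), paste(bad_bond, collapse = ","),
                 paste(bad_chir, collapse = ",")))
  if (strict) return(invisible(TRUE))
  list(ok = ok, bad_backbone = bad_bb, bad_bonds = bad_bond, bad_chirality = bad_chir)
}

#' Write a helix to a PDB file
#'
#' ATOM records with occupancy 1.00 and B-factor 0.00; a REMARK line declares
#' the chirality (D-residues keep standard residue names).
#'
#' @param h an `atomic_helix`.
#' @param file output path.
#' @return invisibly `file`.
#' @export
write_helix_pdb <- function(h, file) {
  a <- h$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = rep(h$chain_id, nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  txt <- readLines(file)
  txt <- c(sprintf("REMARK 999 CHIRALITY %s", h$chirality), txt)
  writeLines(txt, file)
  invisible(file)
}

#' Read a helix (single chain) from a PDB file
#'
#' @param file PDB path.
#' @param chain chain identifier; default: first chain in the file.
#' @return an `atomic_helix`. Chirality is taken from a
#'   `REMARK 999 CHIRALITY` line when present, else `"L"`.
#' @export
read_helix_pdb <- function(file, chain = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain & at$resid %in% names(.AA_ONE), , drop = FALSE]
  if (nrow(at) == 0) stop("no standard protein residues on chain ", chain)
  key <- paste(at$resno, at$insert)
  ridx <- match(key, unique(key))
  atoms <- data.frame(residue_index = ridx, resno = at$resno, resname = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms <- atoms[atoms$elety %in% unlist(lapply(aa_one(atoms$resname), residue_atom_names)) |
                   atoms$elety %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  chir <- "L"
  hdr <- tryCatch(readLines(file, n = 50), error = function(e) character(0))
  m <- grep("^REMARK 999 CHIRALITY", hdr, value = TRUE)
  if (length(m)) chir <- sub(".*CHIRALITY\\s+", "", m[1])
  atomic_helix(atoms, chirality = if (chir %in% c("L", "D")) chir else "L",
               chain_id = chain)
}
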