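# Internal-coordinate <-> Cartesian conversion and the mirror (L/D) transform.
#
# The feature map carries angles only, so reconstruction re-idealizes every
# bond length (and the fixed backbone/side-chain angles of the topology
# table); conversely measure_internal extracts exactly the angles the
# encoding uses, so the two operations round-trip.

#' Internal coordinates of an ideal alpha-helix
#'
#' Backbone torsions fixed at the canonical right-handed helix values
#' (-57, -47, 180 degrees), ideal main-chain bond angles, chi slots at the
#' gauche- rotamer.
#'
#' @param L number of residues.
#' @param phi,psi,omega backbone torsions in degrees.
#' @param seq optional one-letter codes; when given, chi slots up to each
#'   residue's rotamer count are activated at the gauche- rotamer. Without a
#'   sequence all chi slots are masked and reconstruction falls back to its
#'   gauche- default.
#' @return a `helix_ics`.
#' @export
ideal_helix_ics <- function(L, phi = -57, psi = -47, omega = 180, seq = NULL) {
  chi_mask <- if (is.null(seq)) matrix(FALSE, L, 5) else default_chi_mask(.split_seq(seq))
  helix_ics(phi = rep(.deg(phi), L), psi = rep(.deg(psi), L),
            omega = rep(.deg(omega), L),
            tau_n = rep(.IDEAL$tau_n, L), tau_ca = rep(.IDEAL$tau_ca, L),
            tau_c = rep(.IDEAL$tau_c, L),
            chi = matrix(.IDEAL$chi, L, 5), chi_mask = chi_mask)
}

#' Build an ideal alpha-helix for a sequence
#'
#' @param seq one-letter residue codes (vector or single string).
#' @param resno_start author numbering of the first residue.
#' @param ... passed to [ideal_helix_ics()].
#' @return an `atomic_helix`.
#' @export
ideal_helix <- function(seq, resno_start = 1L, ...) {
  seq <- .split_seq(seq)
  reconstruct(seq, ideal_helix_ics(length(seq), seq = seq, ...),
              resno_start = resno_start)
}

.split_seq <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  aa_one(seq)
}

#' Reconstruct a full-atom helix from internal coordinates
#'
#' Sequential natural-extension placement of the backbone (N, CA, C, O) using
#' fixed ideal bond lengths and the supplied bond angles and torsions, then
#' side-chain heavy atoms from the chi slots and the per-residue-type topology
#' table. The result always has L chirality; use [mirror_transform()] for
#' D-helices. Masked angles that the placement needs fall back to ideal
#' helix values (chi slots to the gauche- rotamer).
#'
#' @param seq one-letter residue codes (vector or single string) of length L.
#' @param ics a `helix_ics` of the same length.
#' @param chain_id,resno_start chain id and author number of the first residue.
#' @return an `atomic_helix` with chirality `"L"`.
#' @export
reconstruct <- function(seq, ics, chain_id = "A", resno_start = 1L) {
  seq <- .split_seq(seq)
  L <- length(seq)
  if (length(ics) != L) stop("seq and ics lengths differ (", L, " vs ", length(ics), ")")
  nchi <- chi_count(seq)
  extra <- which(vapply(seq_len(L),
                        function(i) any(ics$chi_mask[i, seq_len(5) > nchi[i]]),
                        logical(1)))
  if (length(extra))
    stop("chi provided for a slot the residue type lacks at residue(s): ",
         paste(extra, collapse = ", "))

  val <- function(nm, i) if (ics$bb_mask[i, nm]) ics[[nm]][i] else .IDEAL[[nm]]
  chi_val <- function(i, k) {
    if (k <= nchi[i] && ics$chi_mask[i, k]) ics$chi[i, k] else .IDEAL$chi
  }

  b <- .BB
  res_atoms <- vector("list", L)
  # backbone seed in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(b$b_n_ca, 0, 0)
  tca <- val("tau_ca", 1L)
  C <- CA + b$b_ca_c * c(-cos(tca), sin(tca), 0)

  for (i in seq_len(L)) {
    psi <- val("psi", i)
    O <- place_atom(N, CA, C, b$b_c_o, .deg(b$a_ca_c_o), wrap_angle(psi + pi))
    pos <- list(N = N, CA = CA, C = C, O = O)
    if (seq[i] != "G") {
      pos$CB <- place_atom(C, N, CA, b$b_ca_cb, .deg(b$a_n_ca_cb), .deg(b$d_c_n_ca_cb))
      for (e in .SIDECHAIN[[seq[i]]]) {
        tors <- if (is.na(e$chi)) .deg(e$fixed) else
          wrap_angle(chi_val(i, e$chi) + .deg(e$offset))
        pos[[e$name]] <- place_atom(pos[[e$a]], pos[[e$b]], pos[[e$c]],
                                    e$bond, .deg(e$angle), tors)
      }
    }
    res_atoms[[i]] <- pos
    if (i < L) {
      Nn <- place_atom(N, CA, C, b$b_c_n, val("tau_c", i), psi)
      CAn <- place_atom(CA, C, Nn, b$b_n_ca, val("tau_n", i + 1L), val("omega", i))
      Cn <- place_atom(C, Nn, CAn, b$b_ca_c, val("tau_ca", i + 1L), val("phi", i + 1L))
      N <- Nn; CA <- CAn; C <- Cn
    }
  }

  nm <- unlist(lapply(res_atoms, names), use.names = FALSE)
  xyz <- do.call(rbind, lapply(res_atoms, function(p) do.call(rbind, p)))
  nat <- vapply(res_atoms, length, 0L)
  atoms <- data.frame(residue_index = rep(seq_len(L), nat),
                      resno = rep(resno_start - 1L + seq_len(L), nat),
                      resname = rep(aa_three(seq), nat),
                      elety = nm, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  atomic_helix(atoms, chirality = "L", chain_id = chain_id)
}

#' Measure the internal coordinates of a full-atom helix
#'
#' Dihedrals by the standard four-atom signed formula; terminal angles that
#' need atoms outside the chain are masked, except the last residue's psi,
#' which is recovered from the carbonyl O. Chi slots beyond the residue's
#' rotamer count are masked; degenerate (collinear) dihedrals are returned as
#' masked values, never NaN.
#'
#' @param h an `atomic_helix` satisfying chain continuity.
#' @param check_continuity reject chains whose C(i)-N(i+1) distances fall
#'   outside the peptide-bond range (default TRUE).
#' @return `list(seq = <one-letter codes>, ics = <helix_ics>)`.
#' @export
measure_internal <- function(h, check_continuity = TRUE) {
  L <- length(h)
  seq <- helix_seq(h)
  N <- atom_by_residue(h, "N"); CA <- atom_by_residue(h, "CA")
  C <- atom_by_residue(h, "C"); O <- atom_by_residue(h, "O")
  miss <- which(apply(is.na(N) | is.na(CA) | is.na(C) | is.na(O), 1, any))
  if (length(miss))
    stop("missing backbone atom(s) at residue index: ", paste(miss, collapse = ", "))
  if (check_continuity && L > 1L) {
    d <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-L, , drop = FALSE])^2))
    bad <- which(d < 1.2 | d > 1.5)
    if (length(bad))
      stop("chain break (C-N distance outside [1.2, 1.5] A) after residue index: ",
           paste(bad, collapse = ", "))
  }

  phi <- psi <- omega <- tau_n <- tau_ca <- tau_c <- numeric(L)
  bb_mask <- matrix(TRUE, L, 6, dimnames = list(NULL, .BB_ANGLE_NAMES))
  if (L > 1L) {
    ii <- 2:L
    phi[ii] <- dihedral_angle_many(C[ii - 1L, , drop = FALSE], N[ii, , drop = FALSE],
                                   CA[ii, , drop = FALSE], C[ii, , drop = FALSE])
    jj <- 1:(L - 1L)
    psi[jj] <- dihedral_angle_many(N[jj, , drop = FALSE], CA[jj, , drop = FALSE],
                                   C[jj, , drop = FALSE], N[jj + 1L, , drop = FALSE])
    omega[jj] <- dihedral_angle_many(CA[jj, , drop = FALSE], C[jj, , drop = FALSE],
                                     N[jj + 1L, , drop = FALSE], CA[jj + 1L, , drop = FALSE])
    tau_n[ii] <- bond_angle_many(C[ii - 1L, , drop = FALSE], N[ii, , drop = FALSE],
                                 CA[ii, , drop = FALSE])
    tau_c[jj] <- bond_angle_many(CA[jj, , drop = FALSE], C[jj, , drop = FALSE],
                                 N[jj + 1L, , drop = FALSE])
  }
  psi[L] <- wrap_angle(dihedral_angle(N[L, ], CA[L, ], C[L, ], O[L, ]) - pi)
  tau_ca[] <- bond_angle_many(N, CA, C)
  bb_mask[1L, c("phi", "tau_n")] <- FALSE
  bb_mask[L, c("omega", "tau_c")] <- FALSE

  chi <- matrix(0, L, 5)
  chi_mask <- matrix(FALSE, L, 5)
  for (i in seq_len(L)) {
    defs <- .CHI_DEFS[[seq[i]]]
    if (is.null(defs)) next
    rc <- residue_coords(h, i)
    for (k in seq_along(defs)) {
      atoms <- defs[[k]]
      if (!all(atoms %in% rownames(rc))) next
      v <- dihedral_angle(rc[atoms[1], ], rc[atoms[2], ], rc[atoms[3], ], rc[atoms[4], ])
      if (!is.na(v)) { chi[i, k] <- v; chi_mask[i, k] <- TRUE }
    }
  }
  # degenerate backbone dihedrals -> masked, never NaN
  for (nm in c("phi", "psi", "omega")) {
    v <- get(nm)
    bad <- is.na(v)
    v[bad] <- 0; bb_mask[bad, nm] <- FALSE
    assign(nm, v)
  }
  list(seq = seq,
       ics = helix_ics(phi, psi, omega, tau_n, tau_ca, tau_c, chi,
                       bb_mask = bb_mask, chi_mask = chi_mask))
}

#' Mirror (L <-> D) transformation
#'
#' Reflects all coordinates through the xy-plane and flips the chirality flag.
#' The reflection is an isometry: all bond lengths, bond angles and pairwise
#' distances are preserved while every dihedral changes sign, converting an
#' L-helix into its D-enantiomer (and back: the transform is an involution).
#'
#' @param h an `atomic_helix`.
#' @return the mirrored `atomic_helix`.
#' @export
mirror_transform <- function(h) {
  h$atoms$z <- -h$atoms$z
  h$chirality <- if (h$chirality == "L") "D" else "L"
  h
}
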