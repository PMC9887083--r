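# Kabsch superposition, partial-alignment RMSD and Ramachandran
# classification.

#' Least-squares superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `mobile` onto `reference`
#' in the least-squares sense, via SVD of the covariance matrix with the
#' determinant correction, so an improper rotation (reflection) is never
#' returned. Chirality therefore matters: a structure and its mirror image
#' give a strictly positive RMSD unless the points are planar.
#'
#' @param mobile,reference n x 3 coordinate matrices, paired by row, n >= 3.
#' @return a `superposition` list: `rotation` (3 x 3, det +1), `translation`
#'   (length-3, applied after rotation), `rmsd` (Angstrom), `atom_count`, and
#'   `degenerate` (TRUE when the point set is collinear, in which case the
#'   rotation about the common axis is arbitrary).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.numeric(mobile) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinate sets must be n x 3 matrices")
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("atom counts differ")
  if (n < 3) stop("need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)          # proper rotation: det(R) = +1
  # collinear input: two near-zero singular values of the centered coords
  s_pts <- svd(A, nu = 0, nv = 0)$d
  degenerate <- sum(s_pts > max(s_pts) * 1e-8) < 2
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd, atom_count = n, degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, rmsd %.4f A%s\n", x$atom_count, x$rmsd,
              if (x$degenerate) " (degenerate: collinear points)" else ""))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition`.
#' @param xyz n x 3 matrix.
#' @return the transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, `+`)
}

# Atom subset used for hotspot matching: backbone + all side-chain heavy
# atoms ("all_heavy"), or N/CA/C/O only ("backbone").
.match_atoms <- function(aa, atom_mode = c("all_heavy", "backbone")) {
  atom_mode <- match.arg(atom_mode)
  if (atom_mode == "backbone") c("N", "CA", "C", "O") else residue_atom_names(aa)
}

#' Partial-alignment RMSD between a generated helix and target hotspots
#'
#' Superposes the union of the matched residues' atoms (backbone N, CA, C, O
#' plus all side-chain heavy atoms by default) onto the hotspot reference
#' coordinates and reports the RMSD. The matching rule requires residue
#' identity: an assignment placing a hotspot on a residue of a different type
#' is rejected.
#'
#' @param generated an `atomic_helix`.
#' @param target a `hotspot_spec`.
#' @param assignment integer vector: position in `generated` of each hotspot.
#' @param atom_mode `"all_heavy"` (default) or `"backbone"`.
#' @return RMSD in Angstrom (attribute `superposition` carries the transform).
#' @export
partial_rmsd <- function(generated, target, assignment,
                         atom_mode = c("all_heavy", "backbone")) {
  atom_mode <- match.arg(atom_mode)
  k <- length(target$types)
  stopifnot(length(assignment) == k)
  if (anyDuplicated(assignment)) stop("assignment positions must be distinct")
  seq <- helix_seq(generated)
  mism <- which(seq[assignment] != target$types)
  if (length(mism))
    stop("residue-type mismatch under assignment at hotspot(s): ",
         paste(mism, collapse = ", "))
  mob <- ref <- vector("list", k)
  for (j in seq_len(k)) {
    nms <- .match_atoms(target$types[j], atom_mode)
    rc <- residue_coords(generated, assignment[j])
    tc <- target$coords[[j]]
    nms <- nms[nms %in% rownames(rc) & nms %in% rownames(tc)]
    mob[[j]] <- rc[nms, , drop = FALSE]
    ref[[j]] <- tc[nms, , drop = FALSE]
  }
  sp <- superpose(do.call(rbind, mob), do.call(rbind, ref))
  structure(sp$rmsd, superposition = sp)
}

#' Ramachandran region of a (phi, psi) pair
#'
#' Rectangular-region classification with mirror-symmetric boxes: alpha_R is
#' phi in (-100, -30), psi in (-80, -5) degrees; alpha_L is its point
#' reflection; beta is phi in (-180, -45) with psi in (45, 180] or
#' (-180, -150); anything else is "other".
#'
#' @param phi,psi angles in radians (vectorized).
#' @return character vector of labels `alpha_R`, `alpha_L`, `beta`, `other`.
#' @export
ramachandran_class <- function(phi, psi) {
  p <- phi * 180 / pi; s <- psi * 180 / pi
  out <- rep("other", length(p))
  out[p > -100 & p < -30 & s > -80 & s < -5] <- "alpha_R"
  out[p > 30 & p < 100 & s > 5 & s < 80] <- "alpha_L"
  beta <- (p > -180 & p < -45) & ((s > 45 & s <= 180) | (s > -180 & s < -150))
  out[beta & out == "other"] <- "beta"
  out
}
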