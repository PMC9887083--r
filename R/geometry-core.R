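# Low-level vector geometry: torsions, bond angles, natural-extension atom
# placement. All angles are radians internally; the IUPAC sign convention is
# used throughout (right-handed, cis = 0).

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the principal interval.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi + 1e-15 & !is.na(y)] <- pi   # boundary maps to +pi, not -pi
  y
}

# Signed dihedral for one atom quadruple; returns NA for (near-)collinear
# configurations instead of propagating NaN.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  n1n <- .norm3(n1); n2n <- .norm3(n2)
  if (n1n < 1e-9 || n2n < 1e-9) return(NA_real_)
  m <- .cross(n1, b2 / .norm3(b2))
  atan2(sum(m * n2), sum(n1 * n2))
}

# Vectorized dihedrals: p1..p4 are n x 3 matrices of atom positions.
dihedral_angle_many <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- sqrt(rowSums(b2 * b2))
  m <- cr(n1, b2 / b2n)
  x <- rowSums(n1 * n2); y <- rowSums(m * n2)
  out <- atan2(y, x)
  bad <- sqrt(rowSums(n1 * n1)) < 1e-9 | sqrt(rowSums(n2 * n2)) < 1e-9
  out[bad] <- NA_real_
  out
}

# Bond angle at b for a-b-c.
bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (.norm3(u) * .norm3(v))
  acos(max(-1, min(1, cosang)))
}

bond_angle_many <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  acos(pmax(-1, pmin(1, cosang)))
}

# Natural-extension (NeRF) placement: position atom D bonded to C given the
# chain A-B-C, the bond length |C-D|, the bond angle B-C-D and the dihedral
# A-B-C-D. Consistent with dihedral_angle: measuring A,B,C,D back returns
# exactly the supplied torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- .unit(c - b)
  n <- .cross(b - a, bc)
  nn <- .norm3(n)
  if (nn < 1e-9) {
    # a,b,c collinear: torsion undefined; pick an arbitrary perpendicular
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- .cross(ref, bc)
    nn <- .norm3(n)
  }
  n <- n / nn
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          -bond * sin(angle) * sin(torsion))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}
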