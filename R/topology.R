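# Amino-acid alphabet, ideal backbone geometry and side-chain topology.
#
# All side-chain geometry is idealized: bond lengths and angles follow standard
# small-molecule/protein dictionary values, dihedrals come either from the chi
# angles carried in the internal-coordinate record or from fixed planar values
# (rings, amide/carboxylate/guanidinium groups).

#' Standard amino-acid alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order. This order
#' defines the columns of the sequence block of the feature map and the
#' tie-break rule of the argmax decoder.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

.AA_THREE <- c(A="ALA", C="CYS", D="ASP", E="GLU", F="PHE", G="GLY", H="HIS",
               I="ILE", K="LYS", L="LEU", M="MET", N="ASN", P="PRO", Q="GLN",
               R="ARG", S="SER", T="THR", V="VAL", W="TRP", Y="TYR")
.AA_ONE <- stats::setNames(names(.AA_THREE), .AA_THREE)

#' Convert between one- and three-letter residue codes
#'
#' @param x character vector of codes.
#' @return character vector of the converted codes.
#' @export
aa_three <- function(x) {
  out <- .AA_THREE[toupper(x)]
  if (anyNA(out)) stop("unknown residue type: ", paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 1L, x, .AA_ONE[x])
  if (anyNA(out) || !all(out %in% AA_ALPHABET))
    stop("unknown residue type: ", paste(x[is.na(out) | !(out %in% AA_ALPHABET)], collapse = ", "))
  unname(out)
}

# Number of active chi slots per residue type (5 slots are always carried in
# the encoding; slots beyond this count are masked).
.CHI_COUNT <- c(A=0L, G=0L, S=1L, C=1L, T=1L, V=1L,
                P=2L, D=2L, N=2L, H=2L, I=2L, L=2L, F=2L, W=2L, Y=2L,
                E=3L, Q=3L, M=3L, K=4L, R=4L)

#' Number of side-chain chi angles of a residue type
#'
#' @param aa one-letter (or three-letter) residue codes.
#' @return integer vector of chi counts (0..4).
#' @export
chi_count <- function(aa) unname(.CHI_COUNT[aa_one(aa)])

# Ideal backbone geometry (Angstrom, degrees). Bond lengths are never part of
# the feature map; reconstruction re-idealizes them.
.BB <- list(
  b_n_ca  = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_c_n_ca = 121.7,   # tau_n
  a_n_ca_c = 111.2,   # tau_ca
  a_ca_c_n = 116.2,   # tau_c
  a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5,
  # dihedral C-N-CA-CB fixing the L-configuration at CA (improper
  # N-CA-C-CB comes out negative; mirrored structures flip it).
  d_c_n_ca_cb = -122.6
)

.deg <- function(x) x * pi / 180

# Masked-but-needed angles fall back to ideal helix values.
.IDEAL <- list(phi = .deg(-57), psi = .deg(-47), omega = pi,
               tau_n = .deg(.BB$a_c_n_ca), tau_ca = .deg(.BB$a_n_ca_c),
               tau_c = .deg(.BB$a_ca_c_n), chi = .deg(-60))

# Side-chain heavy-atom topology beyond CB. Each atom is placed by
# natural-extension from three previously placed atoms (a, b, c; the new atom
# bonds c): bond |c-new|, angle b-c-new (deg), and a dihedral a-b-c-new that is
# either a chi slot plus an offset or a fixed value (deg).
.sc <- function(name, a, b, c, bond, angle, chi = NA_integer_, offset = 0, fixed = NA_real_)
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       chi = chi, offset = offset, fixed = fixed)

.SIDECHAIN <- list(
  G = list(), A = list(),
  S = list(.sc("OG",  "N","CA","CB", 1.417, 110.8, chi = 1L)),
  C = list(.sc("SG",  "N","CA","CB", 1.808, 114.4, chi = 1L)),
  T = list(.sc("OG1", "N","CA","CB", 1.433, 109.6, chi = 1L),
           .sc("CG2", "N","CA","CB", 1.521, 110.5, chi = 1L, offset = -120)),
  V = list(.sc("CG1", "N","CA","CB", 1.527, 110.5, chi = 1L),
           .sc("CG2", "N","CA","CB", 1.527, 110.5, chi = 1L, offset = 120)),
  L = list(.sc("CG",  "N","CA","CB", 1.530, 116.3, chi = 1L),
           .sc("CD1", "CA","CB","CG", 1.521, 110.7, chi = 2L),
           .sc("CD2", "CA","CB","CG", 1.521, 110.7, chi = 2L, offset = 120)),
  I = list(.sc("CG1", "N","CA","CB", 1.530, 110.4, chi = 1L),
           .sc("CG2", "N","CA","CB", 1.521, 110.5, chi = 1L, offset = -120),
           .sc("CD1", "CA","CB","CG1", 1.513, 113.8, chi = 2L)),
  P = list(.sc("CG",  "N","CA","CB", 1.495, 104.5, chi = 1L),
           .sc("CD",  "CA","CB","CG", 1.507, 106.1, chi = 2L)),
  D = list(.sc("CG",  "N","CA","CB", 1.516, 112.6, chi = 1L),
           .sc("OD1", "CA","CB","CG", 1.249, 118.4, chi = 2L),
           .sc("OD2", "CA","CB","CG", 1.249, 118.4, chi = 2L, offset = 180)),
  N = list(.sc("CG",  "N","CA","CB", 1.516, 112.6, chi = 1L),
           .sc("OD1", "CA","CB","CG", 1.231, 120.8, chi = 2L),
           .sc("ND2", "CA","CB","CG", 1.328, 116.4, chi = 2L, offset = 180)),
  E = list(.sc("CG",  "N","CA","CB", 1.530, 114.1, chi = 1L),
           .sc("CD",  "CA","CB","CG", 1.516, 112.6, chi = 2L),
           .sc("OE1", "CB","CG","CD", 1.249, 118.4, chi = 3L),
           .sc("OE2", "CB","CG","CD", 1.249, 118.4, chi = 3L, offset = 180)),
  Q = list(.sc("CG",  "N","CA","CB", 1.530, 114.1, chi = 1L),
           .sc("CD",  "CA","CB","CG", 1.516, 112.6, chi = 2L),
           .sc("OE1", "CB","CG","CD", 1.231, 120.8, chi = 3L),
           .sc("NE2", "CB","CG","CD", 1.328, 116.4, chi = 3L, offset = 180)),
  M = list(.sc("CG",  "N","CA","CB", 1.530, 114.1, chi = 1L),
           .sc("SD",  "CA","CB","CG", 1.803, 112.7, chi = 2L),
           .sc("CE",  "CB","CG","SD", 1.791, 100.9, chi = 3L)),
  K = list(.sc("CG",  "N","CA","CB", 1.530, 114.1, chi = 1L),
           .sc("CD",  "CA","CB","CG", 1.520, 111.3, chi = 2L),
           .sc("CE",  "CB","CG","CD", 1.520, 111.3, chi = 3L),
           .sc("NZ",  "CG","CD","CE", 1.489, 111.9, chi = 4L)),
  R = list(.sc("CG",  "N","CA","CB", 1.530, 114.1, chi = 1L),
           .sc("CD",  "CA","CB","CG", 1.520, 111.3, chi = 2L),
           .sc("NE",  "CB","CG","CD", 1.461, 112.0, chi = 3L),
           .sc("CZ",  "CG","CD","NE", 1.329, 124.2, chi = 4L),
           .sc("NH1", "CD","NE","CZ", 1.326, 120.0, fixed = 0),
           .sc("NH2", "CD","NE","CZ", 1.326, 120.0, fixed = 180)),
  H = list(.sc("CG",  "N","CA","CB", 1.504, 113.8, chi = 1L),
           .sc("ND1", "CA","CB","CG", 1.378, 122.7, chi = 2L),
           .sc("CD2", "CA","CB","CG", 1.354, 131.0, chi = 2L, offset = 180),
           .sc("CE1", "CB","CG","ND1", 1.320, 109.3, fixed = 180),
           .sc("NE2", "CB","CG","CD2", 1.374, 107.2, fixed = 180)),
  F = list(.sc("CG",  "N","CA","CB", 1.502, 113.8, chi = 1L),
           .sc("CD1", "CA","CB","CG", 1.384, 120.8, chi = 2L),
           .sc("CD2", "CA","CB","CG", 1.384, 120.8, chi = 2L, offset = 180),
           .sc("CE1", "CB","CG","CD1", 1.382, 120.7, fixed = 180),
           .sc("CE2", "CB","CG","CD2", 1.382, 120.7, fixed = 180),
           .sc("CZ",  "CG","CD1","CE1", 1.382, 120.0, fixed = 0)),
  Y = list(.sc("CG",  "N","CA","CB", 1.502, 113.8, chi = 1L),
           .sc("CD1", "CA","CB","CG", 1.384, 120.8, chi = 2L),
           .sc("CD2", "CA","CB","CG", 1.384, 120.8, chi = 2L, offset = 180),
           .sc("CE1", "CB","CG","CD1", 1.382, 120.7, fixed = 180),
           .sc("CE2", "CB","CG","CD2", 1.382, 120.7, fixed = 180),
           .sc("CZ",  "CG","CD1","CE1", 1.382, 120.0, fixed = 0),
           .sc("OH",  "CD1","CE1","CZ", 1.376, 119.9, fixed = 180)),
  W = list(.sc("CG",  "N","CA","CB", 1.498, 113.6, chi = 1L),
           .sc("CD1", "CA","CB","CG", 1.365, 126.9, chi = 2L),
           .sc("CD2", "CA","CB","CG", 1.433, 126.7, chi = 2L, offset = 180),
           .sc("NE1", "CB","CG","CD1", 1.374, 110.2, fixed = 180),
           .sc("CE2", "CB","CG","CD2", 1.409, 107.2, fixed = 180),
           .sc("CE3", "CB","CG","CD2", 1.398, 133.9, fixed = 0),
           .sc("CZ2", "CG","CD2","CE2", 1.394, 122.4, fixed = 180),
           .sc("CZ3", "CG","CD2","CE3", 1.382, 118.7, fixed = 180),
           .sc("CH2", "CD2","CE2","CZ2", 1.368, 117.5, fixed = 0))
)

# Atom quadruples defining each measurable chi angle, per residue type.
.CHI_DEFS <- list(
  S = list(c("N","CA","CB","OG")),
  C = list(c("N","CA","CB","SG")),
  T = list(c("N","CA","CB","OG1")),
  V = list(c("N","CA","CB","CG1")),
  P = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD")),
  D = list(c("N","CA","CB","CG"),  c("CA","CB","CG","OD1")),
  N = list(c("N","CA","CB","CG"),  c("CA","CB","CG","OD1")),
  H = list(c("N","CA","CB","CG"),  c("CA","CB","CG","ND1")),
  I = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  L = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD1")),
  F = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD1")),
  W = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD1")),
  Y = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD1")),
  E = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD"),  c("CB","CG","CD","OE1")),
  Q = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD"),  c("CB","CG","CD","OE1")),
  M = list(c("N","CA","CB","CG"),  c("CA","CB","CG","SD"),  c("CB","CG","SD","CE")),
  K = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD"),
           c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  R = list(c("N","CA","CB","CG"),  c("CA","CB","CG","CD"),
           c("CB","CG","CD","NE"), c("CG","CD","NE","CZ"))
)

#' Heavy-atom names of a residue type
#'
#' Backbone (N, CA, C, O), CB for everything but glycine, then the side-chain
#' atoms of the internal topology table, in placement order.
#'
#' @param aa a single residue code.
#' @return character vector of atom names.
#' @export
residue_atom_names <- function(aa) {
  aa <- aa_one(aa)
  nm <- c("N", "CA", "C", "O")
  if (aa != "G") nm <- c(nm, "CB")
  c(nm, vapply(.SIDECHAIN[[aa]], `[[`, "", "name"))
}

# Helix-propensity weights used by the synthetic corpus generator. Relative
# weights follow the usual experimental propensity ordering (A/L/E/K/M/Q/R/I
# helix formers enriched, G and beta-branched residues depleted). Proline is
# excluded from interior positions and only allowed, rarely, at position 1.
.HELIX_PROPENSITY <- c(A=0.105, C=0.015, D=0.045, E=0.095, F=0.040, G=0.025,
                       H=0.020, I=0.055, K=0.080, L=0.105, M=0.030, N=0.035,
                       P=0.000, Q=0.055, R=0.060, S=0.045, T=0.045, V=0.050,
                       W=0.015, Y=0.030)

# Canonical rotamer means (deg) the synthetic generator draws chi angles from:
# gauche-, trans, gauche+ with helix-like weights.
.ROTAMER_MEANS  <- c(-60, 180, 60)
.ROTAMER_WEIGHTS <- c(0.5, 0.35, 0.15)
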